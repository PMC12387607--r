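# Architecture construction, parameter counting, tiling and training
# mechanics.

test_that("configuration validation enforces the printed ranges", {
  expect_error(dpnet_config(dfe_kernels = c(7, 3, 3, 3, 1, 5, 3, 1, 1)),
               "1\\.\\.5")
  expect_error(dpnet_config(cfe_kernels = c(3, 7, 7, 9, 23, 13, 9, 5, 5, 5)),
               "5\\.\\.23")
  expect_error(dpnet_config(dfe_filters = c(80, 8, 23, 4, 22, 25, 26, 16, 64)),
               "64")
  expect_error(dpnet_config(fusion_kernels = c(2, 1)), "odd")
})

test_that("per-layer parameter counts follow the counting convention", {
  tab <- network_layer_table(dpnet_config())
  # first detailed-path layer: 5x5 conv, 3 -> 27 channels, plus its BN
  expect_equal(tab$params[tab$type == "conv"][1], 25 * 3 * 27 + 27)
  expect_equal(tab$params[tab$type == "bn"][1], 2 * 27)
  # additivity: the total is the sum of the per-layer counts
  expect_identical(count_parameters(dpnet_config()), as.integer(sum(tab$params)))
  # path structure: 9 + 10 + 2 convolutions
  expect_equal(sum(tab$type == "conv" & tab$path == "dfe"), 9)
  expect_equal(sum(tab$type == "conv" & tab$path == "cfe"), 10)
  expect_equal(sum(tab$type == "conv" & tab$path == "fusion"), 2)
  # path budgets
  expect_equal(sum(tab$params[tab$path == "dfe"]), 41133)
  expect_equal(sum(tab$params[tab$path == "cfe"]), 101268)
  expect_equal(sum(tab$params[tab$path == "fusion"]), 10000)
})

test_that("a built model counts the same parameters as its configuration", {
  cfg <- dpnet_config()
  model <- build_network(cfg, seed = 5)
  expect_identical(count_parameters(model), count_parameters(cfg))
  # fully convolutional: the count does not depend on the input size
  st <- channel_stats(array(runif(64 * 64 * 3, 0, 255), dim = c(64, 64, 3)))
  model$stats <- st
  p1 <- predict_probabilities(model, array(128, dim = c(64, 64, 3)))
  p2 <- predict_probabilities(model, array(128, dim = c(32, 48, 3)))
  expect_identical(count_parameters(model), count_parameters(cfg))
  expect_equal(dim(p1), c(64L, 64L, 3L))
  expect_equal(dim(p2), c(32L, 48L, 3L))
})

test_that("the network maps any input to a per-pixel probability simplex", {
  model <- build_network(dpnet_config(), seed = 2)
  x <- array(rnorm(64 * 64 * 3), dim = c(64, 64, 3, 2))
  p <- nucseg:::cpp_forward(model$nodes, model$weights, x, TRUE)
  expect_equal(dim(p), c(64L, 64L, 3L, 2L))
  expect_true(all(p >= 0))
  expect_lt(max(abs(apply(p, c(1, 2, 4), sum) - 1)), 1e-6)
  cls <- apply(p[, , , 1], c(1, 2), which.max)
  expect_true(all(cls %in% 1:3))
})

test_that("spatial dims not divisible by 16 are rejected with the reason", {
  model <- build_network(dpnet_config(), seed = 1)
  x <- array(rnorm(40 * 40 * 3), dim = c(40, 40, 3, 1))
  expect_error(nucseg:::cpp_forward(model$nodes, model$weights, x, TRUE),
               "even")
  expect_error(nucseg:::check_divisible(40, 64), "4 levels")
})

test_that("patch grids tile exactly and stitching inverts extraction", {
  g <- patch_grid(960, 960)
  expect_equal(nrow(g$origins), 225)  # (960 / 64)^2

  x <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  g1 <- patch_grid(64, 64)
  p <- extract_patches(x, g1)
  expect_equal(dim(p)[4], 1)
  expect_equal(p[, , , 1], x, ignore_attr = TRUE)
  expect_equal(stitch_patches(p, g1), x)

  # non-divisible dims: mirror-pad, tile, stitch, crop restores the input
  y <- array(runif(100 * 70 * 3), dim = c(100, 70, 3))
  g2 <- patch_grid(100, 70)
  expect_equal(stitch_patches(extract_patches(y, g2), g2), y)

  # label maps (2D) round-trip too, and probabilities stay on the simplex
  lab <- matrix(sample(1:3, 100 * 70, TRUE), 100, 70)
  expect_equal(stitch_patches(extract_patches(lab, g2), g2), lab,
               ignore_attr = TRUE)
  expect_error(stitch_patches(extract_patches(y, g2)[, , , 1:3], g2),
               "does not match")
})

test_that("training is deterministic and can overfit one sample", {
  set.seed(10)
  sm <- generate_sample(synth_spec(), 123)
  x <- array(sm$image, dim = c(64, 64, 3, 1))
  y <- array(sm$truth, dim = c(64, 64, 1))
  f1 <- fit_dpnet(x, y, epochs = 2, batch_size = 1, seed = 7)
  f2 <- fit_dpnet(x, y, epochs = 2, batch_size = 1, seed = 7)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$weights, f2$weights)

  expect_error(fit_dpnet(array(0, dim = c(64, 64, 3, 0)), NULL), "empty")

  # overfit sanity: enough capacity to memorize a single tile
  f <- fit_dpnet(x, y, epochs = 150, batch_size = 1, seed = 7)
  pred <- predict(f, sm$image, tta = "none")
  expect_gte(mean(pred == sm$truth), 0.99)
})

test_that("the training loss decreases over the desk-scale run", {
  runs <- pipeline_runs()
  h <- runs[[1]]$history
  expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_lt(min(diff(h$loss)), 0)  # strictly decreasing somewhere
})

test_that("checkpoints round-trip through save/load", {
  sm <- generate_sample(synth_spec(), 5)
  x <- array(sm$image, dim = c(64, 64, 3, 1))
  y <- array(sm$truth, dim = c(64, 64, 1))
  f <- fit_dpnet(x, y, epochs = 1, batch_size = 1, seed = 3)
  path <- file.path(tempdir(), "model.rds")
  save_dpnet(f, path)
  g <- load_dpnet(path)
  expect_identical(g$weights, f$weights)
  expect_true(file.exists(paste0(path, ".yaml")))
  p1 <- predict_probabilities(f, sm$image)
  p2 <- predict_probabilities(g, sm$image)
  expect_identical(p1, p2)
})
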