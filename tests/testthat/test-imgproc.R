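# Colour normalization, enhancement and rotation geometry.

make_rgb <- function(h, w, fill = NULL) {
  if (is.null(fill)) array(runif(h * w * 3, 0, 255), dim = c(h, w, 3))
  else array(fill, dim = c(h, w, 3))
}

test_that("channel statistics match the pooled definition", {
  expect_equal(channel_stats(make_rgb(4, 4, 100))$mu, rep(100, 3))
  expect_equal(channel_stats(make_rgb(4, 4, 100))$delta, rep(0, 3))

  # two-pixel channel {0, 200}: mean 100, population sd 100
  x <- array(0, dim = c(1, 2, 3)); x[1, 2, ] <- 200
  st <- channel_stats(x)
  expect_equal(st$mu, rep(100, 3))
  expect_equal(st$delta, rep(100, 3))

  # pooled over a collection == single-pass arithmetic over all pixels
  set.seed(42)
  imgs <- lapply(1:10, function(i) make_rgb(6, 5))
  st <- channel_stats(imgs)
  for (c in 1:3) {
    pool <- unlist(lapply(imgs, function(im) im[, , c]))
    expect_equal(st$mu[c], mean(pool))
    expect_equal(st$delta[c], sqrt(mean((pool - mean(pool))^2)))
  }
  expect_error(channel_stats(list()), "non-empty")
})

test_that("normalization is the z-score and round-trips exactly", {
  st <- structure(list(mu = c(100, 100, 100), delta = c(25, 25, 25),
                       source = NA, n_pixels = 1),
                  class = "channel_stats")
  x <- make_rgb(2, 2, 150)
  z <- normalize_image(x, st)
  expect_equal(as.numeric(z), rep(2, length(z)))
  expect_equal(normalize_image(make_rgb(3, 3, 100), st),
               make_rgb(3, 3, 0), ignore_attr = TRUE)

  set.seed(1)
  x <- make_rgb(8, 8)
  st <- channel_stats(x)
  expect_lt(max(abs(denormalize_image(normalize_image(x, st)) - x)), 1e-6)

  # normalizing a split by its own stats gives mean 0 / sd 1 per channel
  imgs <- lapply(1:5, function(i) make_rgb(8, 8))
  st <- channel_stats(imgs)
  zs <- lapply(imgs, normalize_image, stats = st)
  for (c in 1:3) {
    pool <- unlist(lapply(zs, function(z) z[, , c]))
    expect_lt(abs(mean(pool)), 1e-6)
    expect_lt(abs(sqrt(mean(pool^2)) - 1), 1e-6)
  }

  # degenerate constant channel survives through the eps floor
  z <- normalize_image(make_rgb(2, 2, 7), channel_stats(make_rgb(2, 2, 7)))
  expect_true(all(is.finite(z)))
})

test_that("edge detection is binary, silent on flat images and localized", {
  expect_true(all(detect_edges(make_rgb(16, 16, 128)) == 0L))

  # vertical two-tone step: edges confined to a band around the step
  x <- make_rgb(32, 32, 40)
  x[, 17:32, ] <- 220
  e <- detect_edges(x)
  expect_true(all(e %in% c(0L, 1L)))
  hit <- which(e == 1L, arr.ind = TRUE)
  expect_gt(nrow(hit), 0)
  expect_true(all(abs(hit[, 2] - 16.5) <= 2.5))  # band of width <= 2 per side

  # Canny commutes with quarter rotations away from the border
  set.seed(3)
  s <- generate_sample(synth_spec(), 77)
  e1 <- rotate_cw(detect_edges(s$image), 1)
  e2 <- detect_edges(rotate_cw(s$image, 1))
  core <- 8:56
  expect_equal(e1[core, core], e2[core, core])
})

test_that("enhancement preserves constants and boosts edges by alpha", {
  x <- make_rgb(16, 16, 90)
  expect_equal(enhance_image(x), x)  # kernel sums to 1, no edges

  # at an edge pixel the pre-clip value gains exactly alpha
  x <- make_rgb(24, 24, 60); x[, 13:24, ] <- 180
  p <- enhance_params(alpha = 20)
  e <- detect_edges(x, p)
  sm <- x
  for (c in 1:3) sm[, , c] <- nucseg:::cpp_filter2_reflect(x[, , c], p$kernel)
  enh <- enhance_image(x, p)
  ij <- which(e == 1L, arr.ind = TRUE)[1, ]
  expect_equal(enh[ij[1], ij[2], 1], sm[ij[1], ij[2], 1] + 20)

  # saturation at 255: output is exactly clip(smoothed + alpha * edges)
  x <- make_rgb(24, 24, 200); x[, 13:24, ] <- 250  # bright step: boost clips
  e <- detect_edges(x, p)
  sm <- x
  for (c in 1:3) sm[, , c] <- nucseg:::cpp_filter2_reflect(x[, , c], p$kernel)
  expected <- sm
  for (c in 1:3) expected[, , c] <- pmin(pmax(sm[, , c] + 20 * e, 0), 255)
  enh <- enhance_image(x, p)
  expect_equal(enh, expected)
  expect_true(any(sm[, , 1][e == 1L] + 20 > 255))  # clipping actually occurs
  expect_true(all(enh <= 255 & enh >= 0))
})

test_that("clockwise rotation follows the exact index map and group law", {
  # 1x2 image [a, b] -> one turn cw -> 2x1 image [a; b]
  x <- matrix(c(1, 2), 1, 2)
  r <- rotate_cw(x, 1)
  expect_equal(dim(r), c(2L, 1L))
  expect_equal(as.numeric(r), c(1, 2))

  set.seed(9)
  m <- matrix(rnorm(35), 5, 7)
  for (a in 0:3) for (b in 0:3)
    expect_identical(rotate_cw(rotate_cw(m, a), b),
                     rotate_cw(m, (a + b) %% 4))
  expect_identical(rotate_cw(m, 4), m)

  # rotate then inverse-rotate a probability map is bit-identical
  p <- array(runif(5 * 7 * 3), dim = c(5, 7, 3))
  for (a in 0:3)
    expect_identical(rotate_cw(rotate_cw(p, a), (4 - a) %% 4), p)
})

test_that("the augmentation set has the fixed five views and exact inverses", {
  set.seed(4)
  x <- make_rgb(16, 24)  # non-square on purpose
  aug <- make_augmentation_set(x)
  expect_length(aug$views, 5)
  expect_identical(aug$views[[1]], x)
  expect_equal(dim(aug$views[[2]])[1:2], c(24L, 16L))  # transposed dims
  expect_equal(dim(aug$views[[3]])[1:2], c(16L, 24L))
  expect_equal(dim(aug$views[[4]])[1:2], c(24L, 16L))
  expect_equal(dim(aug$views[[5]])[1:2], c(16L, 24L))
  expect_identical(aug$inverse_turns, c(0L, 3L, 2L, 1L, 0L))

  # applying each stored inverse to a coordinate grid restores the original
  grid <- array(seq_len(16 * 24 * 3), dim = c(16, 24, 3))
  for (v in 1:4) {
    fwd <- rotate_cw(grid, aug$turns[v])
    expect_identical(rotate_cw(fwd, aug$inverse_turns[v]), grid)
  }

  sq <- make_rgb(64, 64)
  aug <- make_augmentation_set(sq)
  expect_true(all(vapply(aug$views, function(v) all(dim(v) == c(64, 64, 3)),
                         logical(1))))
})
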