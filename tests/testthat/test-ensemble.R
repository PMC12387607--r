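# Averaging and voting ensembles, and the TTA coordinate bookkeeping.

# build a stack of constant-per-pixel probability maps on a dyadic grid so
# convex combinations are exact in floating point
stack_from_vectors <- function(vecs, h = 2, w = 2) {
  maps <- lapply(vecs, function(v) {
    p <- array(0, dim = c(h, w, 3))
    for (k in 1:3) p[, , k] <- v[k]
    p
  })
  prob_stack(maps)
}

test_that("averaging is the pixelwise mean with lowest-index tie-break", {
  # five identical maps: the average is bit-exact the input (dyadic values)
  v <- c(1 / 4, 1 / 4, 1 / 2)
  st <- stack_from_vectors(rep(list(v), 5))
  res <- average_ensemble(st)
  expect_identical(res$pav, st$maps[[1]])
  expect_true(all(res$class_map == 3L))

  # class-1 probabilities (0.2, 0.4, 0.6, 0.8, 1.0) average to 0.6
  vecs <- lapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(p1)
    c(p1, (1 - p1) / 2, (1 - p1) / 2))
  res <- average_ensemble(stack_from_vectors(vecs))
  expect_equal(res$pav[1, 1, 1], 0.6)

  # convex combination stays on the simplex
  set.seed(2)
  maps <- lapply(1:5, function(i) {
    a <- array(runif(4 * 4 * 3), dim = c(4, 4, 3))
    s <- a[, , 1] + a[, , 2] + a[, , 3]
    for (k in 1:3) a[, , k] <- a[, , k] / s
    a
  })
  res <- average_ensemble(prob_stack(maps))
  expect_lt(max(abs(apply(res$pav, c(1, 2), sum) - 1)), 1e-12)

  # argmax tie between classes 1 and 2 resolves to class 1
  res <- average_ensemble(stack_from_vectors(list(c(.375, .375, .25))))
  expect_true(all(res$class_map == 1L))

  expect_error(prob_stack(list(array(1 / 3, c(2, 2, 3)),
                               array(1 / 3, c(3, 3, 3)))), "share dims")
})

test_that("voting takes the majority and falls back to averaging on ties", {
  onehot <- function(k, eps = 0) {
    v <- rep(eps / 2, 3); v[k] <- 1 - eps; v
  }
  # strict majority: votes (1, 1, 1, 2, 3) -> class 1
  st <- stack_from_vectors(list(onehot(1), onehot(1), onehot(1),
                                onehot(2), onehot(3)))
  expect_true(all(vote_ensemble(st) == 1L))

  # tie (1, 1, 2, 2, 3) with the averaged class-2 probability largest:
  # hand enumeration of the five vectors gives means (0.38, 0.40, 0.22)
  vecs <- list(c(.9, .05, .05), c(.6, .3, .1), c(.1, .8, .1),
               c(.2, .7, .1), c(.1, .15, .75))
  means <- colMeans(do.call(rbind, vecs))
  expect_equal(which.max(means), 2L)
  st <- stack_from_vectors(vecs)
  expect_true(all(vote_ensemble(st) == 2L))

  # unanimous votes agree with averaging
  st <- stack_from_vectors(rep(list(onehot(2)), 5))
  expect_identical(vote_ensemble(st), average_ensemble(st)$class_map)
})

test_that("ensembles are invariant to the order of the views", {
  set.seed(5)
  maps <- lapply(1:5, function(i) {
    a <- array(runif(6 * 6 * 3), dim = c(6, 6, 3))
    s <- a[, , 1] + a[, , 2] + a[, , 3]
    for (k in 1:3) a[, , k] <- a[, , k] / s
    a
  })
  perm <- c(4, 1, 5, 3, 2)
  a1 <- average_ensemble(prob_stack(maps))$class_map
  a2 <- average_ensemble(prob_stack(maps[perm]))$class_map
  expect_identical(a1, a2)
  v1 <- vote_ensemble(prob_stack(maps))
  v2 <- vote_ensemble(prob_stack(maps[perm]))
  expect_identical(v1, v2)
})

test_that("TTA with a rotation-equivariant predictor is a fixed point", {
  rule <- color_rule_classifier()
  for (seed in c(21, 22)) {
    sm <- generate_sample(synth_spec(), seed)
    single <- nucseg:::argmax_classes(predict_probabilities(rule, sm$image))
    for (mode in c("average", "vote")) {
      for (nv in c(3, 5)) {
        cm <- run_tta_inference(rule, sm$image, mode = mode, views = nv)
        expect_identical(as.vector(cm), as.vector(single),
                         label = paste(mode, nv, "seed", seed))
        expect_equal(dim(cm), dim(sm$truth))
      }
    }
    # degenerate single-view config reduces to plain prediction
    cm1 <- run_tta_inference(rule, sm$image, mode = "none")
    expect_identical(as.vector(cm1), as.vector(single))
  }
})

test_that("N = 3 uses exactly the original and the 90/270 rotations", {
  seen <- new.env(parent = emptyenv())
  seen$imgs <- list()
  rec <- structure(list(), class = "view_recorder")
  registerS3method("predict_probabilities", "view_recorder",
                   function(model, x, ...) {
                     seen$imgs[[length(seen$imgs) + 1L]] <- x
                     p <- array(0, dim = c(dim(x)[1], dim(x)[2], 3))
                     p[, , 3] <- 1
                     p
                   },
                   envir = asNamespace("nucseg"))
  x <- array(runif(16 * 24 * 3, 0, 255), dim = c(16, 24, 3))  # non-square
  run_tta_inference(rec, x, mode = "average", views = 3)
  expect_length(seen$imgs, 3)
  dims <- vapply(seen$imgs, function(im) dim(im)[1], integer(1))
  expect_equal(sort(dims), c(16L, 24L, 24L))
  # the one H x W view must be the untouched original (not the enhanced one)
  orig <- seen$imgs[[which(dims == 16L)]]
  expect_identical(orig, x)
  # and the two W x H views are the exact 90/270 rotations
  rots <- seen$imgs[dims == 24L]
  expect_true(any(vapply(rots, identical, logical(1), rotate_cw(x, 1))))
  expect_true(any(vapply(rots, identical, logical(1), rotate_cw(x, 3))))
})
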