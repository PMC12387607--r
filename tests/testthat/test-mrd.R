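# Morphological melanoma-region extraction.

test_that("the melanoma mask is the exact class-1 indicator", {
  cm <- matrix(3L, 8, 8)
  expect_true(all(melanoma_mask(cm) == 0L))
  cm[] <- 1L
  expect_true(all(melanoma_mask(cm) == 1L))
  set.seed(1)
  cm <- matrix(sample(1:3, 64, TRUE), 8, 8)
  expect_equal(sum(melanoma_mask(cm)), sum(cm == 1L))
})

test_that("the morphology chain fills holes and drops specks", {
  # solid disk with a small interior hole: hole filled, disk retained
  m <- 1L * outer(1:32, 1:32, function(r, c) (r - 16)^2 + (c - 16)^2 <= 100)
  m[16, 16] <- 0L; m[16, 17] <- 0L  # 2-pixel hole
  p <- morphology_params(dilate_radius = 2, erode_radius = 2, min_area = 10)
  out <- apply_morphology(m, p)
  expect_equal(out, oracle_morphology(m, p))
  expect_true(all(out[m == 1L] == 1L))   # disk retained
  expect_equal(out[16, 16], 1L)          # hole filled
  expect_equal(out[16, 17], 1L)

  # isolated single pixel is removed by the area threshold
  m <- matrix(0L, 20, 20); m[10, 10] <- 1L
  expect_true(all(apply_morphology(m, p) == 0L))

  # empty in, empty out
  expect_true(all(apply_morphology(matrix(0L, 16, 16), p) == 0L))
})

test_that("dilation/erosion match the set definition and its properties", {
  set.seed(7)
  for (i in 1:25) {
    h <- sample(12:40, 1); w <- sample(12:40, 1)
    m <- random_mask(h, w, sample(c("noise", "blobs"), 1))
    r <- sample(1:3, 1)
    se <- disk_se(r)
    dil <- nucseg:::cpp_dilate(m, se)
    ero <- nucseg:::cpp_erode(m, se)
    expect_equal(dil, oracle_dilate(m, se))
    expect_equal(ero, oracle_erode(m, se))
    # extensivity / anti-extensivity
    expect_true(all(dil[m == 1L] == 1L))
    expect_true(all(m[ero == 1L] == 1L))
  }
})

test_that("dilation/erosion agree with an independent implementation", {
  # EBImage as an external cross-check with the same explicit kernel.
  # Its erosion pads the outside with foreground, ours with background
  # (the set definition), so erosion is compared away from the border.
  set.seed(13)
  for (i in 1:10) {
    m <- matrix(rbinom(30 * 25, 1, 0.3), 30, 25)
    r <- sample(1:3, 1)
    se <- disk_se(r)
    expect_equal(nucseg:::cpp_dilate(m, se),
                 matrix(as.integer(EBImage::dilate(m, se * 1)), 30, 25))
    e1 <- nucseg:::cpp_erode(m, se)
    e2 <- matrix(as.integer(EBImage::erode(m, se * 1)), 30, 25)
    core_r <- (1 + r):(30 - r); core_c <- (1 + r):(25 - r)
    expect_equal(e1[core_r, core_c], e2[core_r, core_c])
  }
})

test_that("dilation and erosion are dual through complementation", {
  # on masks with an all-background margin wider than the radius the
  # identity not(erode(A)) == dilate(not(A)) holds on the full frame
  set.seed(8)
  for (i in 1:10) {
    r <- sample(1:2, 1)
    m <- matrix(0L, 24, 24)
    m[(r + 2):(24 - r - 1), (r + 2):(24 - r - 1)] <-
      random_mask(24 - 2 * r - 2, 24 - 2 * r - 2, "blobs")
    se <- disk_se(r)
    lhs <- 1L - nucseg:::cpp_erode(m, se)
    rhs <- nucseg:::cpp_dilate(1L - m, se)
    expect_equal(lhs, rhs)
  }
})

test_that("the chain is idempotent on its own output for equal radii", {
  p <- morphology_params(dilate_radius = 2, erode_radius = 2, min_area = 0)
  set.seed(9)
  fixtures <- list(
    local({ m <- matrix(0L, 40, 40); m[8:20, 8:20] <- 1L; m[25:30, 25:33] <- 1L; m }),
    random_mask(40, 40, "blobs", 0.2),
    random_mask(48, 32, "blobs", 0.35)
  )
  for (m in fixtures) {
    once <- apply_morphology(m, p)
    twice <- apply_morphology(once, p)
    expect_identical(twice, once)
  }
})

test_that("thresholding never increases the component count", {
  set.seed(10)
  for (i in 1:10) {
    m <- random_mask(40, 40, "noise", 0.25)
    p0 <- morphology_params(min_area = 0)
    p1 <- morphology_params(min_area = 15)
    n0 <- max(nucseg:::cpp_label(apply_morphology(m, p0)))
    n1 <- max(nucseg:::cpp_label(apply_morphology(m, p1)))
    expect_lte(n1, n0)
  }
})

test_that("region extraction copies inside the mask and blanks outside", {
  set.seed(11)
  x <- array(runif(8 * 8 * 3, 0, 255), dim = c(8, 8, 3))
  full <- matrix(1L, 8, 8)
  expect_identical(extract_regions(x, full), x)
  empty <- matrix(0L, 8, 8)
  expect_true(all(extract_regions(x, empty) == 0))
  m <- matrix(rbinom(64, 1, 0.5), 8, 8)
  out <- extract_regions(x, m)
  for (c in 1:3) {
    expect_equal(out[, , c][m == 1], x[, , c][m == 1])
    expect_true(all(out[, , c][m == 0] == 0))
  }
  expect_error(extract_regions(x, matrix(0L, 4, 4)), "dims")
})

test_that("the agreement overlay colours match the confusion outcomes", {
  set.seed(12)
  pred <- matrix(rbinom(100, 1, 0.5), 10, 10)
  truth <- matrix(rbinom(100, 1, 0.5), 10, 10)
  ov <- overlay_eval(pred, truth)
  cc <- confusion_from_maps(pred, truth)
  is_col <- function(rgb) {
    apply(ov, c(1, 2), function(v) all(v == rgb))
  }
  expect_equal(sum(is_col(c(255, 255, 255))), cc$tp)
  expect_equal(sum(is_col(c(0, 0, 0))), cc$tn)
  expect_equal(sum(is_col(c(0, 255, 0))), cc$fp)
  expect_equal(sum(is_col(c(128, 0, 128))), cc$fn)

  same <- overlay_eval(truth, truth)
  expect_true(all(apply(same, c(1, 2), function(v)
    all(v == c(255, 255, 255)) || all(v == c(0, 0, 0)))))
  allfp <- overlay_eval(matrix(1L, 4, 4), matrix(0L, 4, 4))
  expect_true(all(allfp[, , 2] == 255) && all(allfp[, , c(1, 3)] == 0))
})

test_that("region tables report component areas and boxes", {
  m <- matrix(0L, 20, 20)
  m[2:5, 2:5] <- 1L      # 16 px
  m[10:12, 14:18] <- 1L  # 15 px
  tab <- region_table(m)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$area, c(16L, 15L))
  b <- tab[tab$area == 15, ]
  expect_equal(c(b$rmin, b$rmax, b$cmin, b$cmax), c(10, 12, 14, 18))
})
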