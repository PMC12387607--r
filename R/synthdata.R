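# Synthetic H&E-like tile generator with exact 3-class ground truth.
#
# Emulates the appearance the pipeline is built for: a pink
# background/cytoplasm field, scattered near-circular blue-purple
# non-melanoma nuclei, and a spatially coherent cluster of larger, darker,
# more elliptical melanoma nuclei, plus additive Gaussian noise.  The truth
# map is the exact painted geometry, so every stage can be trained and
# scored without real slides.

#' Specification of the synthetic tile generator
#'
#' Nucleus sizes are parameterized by a mean radius `r` and an axis ratio
#' `q`: the painted ellipse has semi-axes `r/sqrt(q)` and `r*sqrt(q)`, so
#' its area is exactly `pi * r^2` regardless of `q`.  The melanoma mean
#' radius range must exceed the non-melanoma one.
#'
#' @param tile tile side length in pixels (default 64, the network patch
#'   size; must be positive).
#' @param bg_color,nonmel_color,mel_color mean RGB colours (0..255) of
#'   background/cytoplasm, non-melanoma nuclei and melanoma nuclei.
#' @param color_jitter half-width of the uniform per-nucleus colour jitter
#'   (intensity units).
#' @param noise_sd standard deviation of the additive Gaussian pixel noise.
#' @param n_nonmel expected number of non-melanoma nuclei (Poisson).
#' @param nonmel_radius range of the non-melanoma mean radius (uniform).
#' @param nonmel_axis_ratio axis-ratio range of non-melanoma nuclei
#'   (near 1: near-circular).
#' @param n_mel number of melanoma nuclei (fixed count, so the expected
#'   melanoma area is analytic).
#' @param mel_radius range of the melanoma mean radius (uniform; larger
#'   than `nonmel_radius`).
#' @param mel_axis_ratio axis-ratio range of melanoma nuclei (more
#'   elongated).
#' @param cluster_sd standard deviation (pixels) of the Gaussian scatter of
#'   melanoma nuclei around a single random cluster centre.
#' @param max_tries placement retries per non-melanoma nucleus before
#'   giving up with an error.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(tile = 64,
                       bg_color = c(230, 185, 205),
                       nonmel_color = c(95, 70, 150),
                       mel_color = c(70, 50, 120),
                       color_jitter = 15,
                       noise_sd = 8,
                       n_nonmel = 6,
                       nonmel_radius = c(3, 6),
                       nonmel_axis_ratio = c(0.85, 1),
                       n_mel = 3,
                       mel_radius = c(5, 9),
                       mel_axis_ratio = c(0.5, 0.9),
                       cluster_sd = 14,
                       max_tries = 200) {
  stopifnot(tile >= 16, noise_sd >= 0, color_jitter >= 0,
            length(bg_color) == 3, length(nonmel_color) == 3,
            length(mel_color) == 3,
            all(c(bg_color, nonmel_color, mel_color) >= 0),
            all(c(bg_color, nonmel_color, mel_color) <= 255))
  if (mean(mel_radius) <= mean(nonmel_radius))
    stop("melanoma mean radius must exceed the non-melanoma mean radius")
  structure(list(tile = as.integer(tile), bg_color = bg_color,
                 nonmel_color = nonmel_color, mel_color = mel_color,
                 color_jitter = color_jitter, noise_sd = noise_sd,
                 n_nonmel = n_nonmel, nonmel_radius = nonmel_radius,
                 nonmel_axis_ratio = nonmel_axis_ratio,
                 n_mel = n_mel, mel_radius = mel_radius,
                 mel_axis_ratio = mel_axis_ratio, cluster_sd = cluster_sd,
                 max_tries = max_tries),
            class = "synth_spec")
}

#' Analytically expected melanoma area fraction of a spec
#'
#' With `n_mel` ellipses of area `pi * r^2`, `r ~ U(a, b)`, the expected
#' painted melanoma area (ignoring overlap between nuclei and clipping at
#' the tile border) is `n_mel * pi * E[r^2]`, with
#' `E[r^2] = (b^3 - a^3) / (3 (b - a))`.
#'
#' @param spec a [synth_spec].
#' @return expected class-1 pixel fraction of a tile.
#' @export
expected_melanoma_fraction <- function(spec) {
  a <- spec$mel_radius[1]; b <- spec$mel_radius[2]
  er2 <- if (b > a) (b^3 - a^3) / (3 * (b - a)) else a^2
  spec$n_mel * pi * er2 / spec$tile^2
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

paint_ellipse <- function(S, cx, cy, r, q, theta) {
  # returns logical S x S matrix of pixels inside the rotated ellipse
  a <- r / sqrt(q); b <- r * sqrt(q)
  rows <- matrix(seq_len(S), S, S)          # row index = y
  cols <- matrix(seq_len(S), S, S, byrow = TRUE)
  dx <- cols - cx; dy <- rows - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  u^2 + v^2 <= 1
}

#' Generate one synthetic labelled tile
#'
#' Paints the pink background, scatters non-melanoma nuclei with a
#' minimum-separation retry rule, places the melanoma nuclei around a
#' single Gaussian cluster centre (painted last, so melanoma wins where
#' nuclei overlap), adds Gaussian noise and clips/rounds to 8-bit.  The
#' truth map records the exact painted geometry (1 = melanoma,
#' 2 = non-melanoma, 3 = background).  Identical `spec` and `seed` give a
#' bit-identical sample.
#'
#' @param spec a [synth_spec].
#' @param seed integer seed for this sample.
#' @return an object of class `labeled_sample`: list with `image`
#'   (`tile x tile x 3`, 0..255 integers stored as doubles), `truth`
#'   (`tile x tile` integer matrix in 1..3), `spec` and `seed`.
#' @export
generate_sample <- function(spec = synth_spec(), seed = 1L) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(seed, {
    S <- spec$tile
    img <- array(rep(spec$bg_color, each = S * S), dim = c(S, S, 3))
    lab <- matrix(3L, S, S)

    # non-melanoma nuclei: uniform placement with a separation retry rule
    n_nm <- rpois(1, spec$n_nonmel)
    centers <- matrix(numeric(0), ncol = 3)  # cx, cy, r
    for (i in seq_len(n_nm)) {
      r <- runif(1, spec$nonmel_radius[1], spec$nonmel_radius[2])
      placed <- FALSE
      for (try in seq_len(spec$max_tries)) {
        cx <- runif(1, 1 + r, S - r); cy <- runif(1, 1 + r, S - r)
        if (nrow(centers) == 0 ||
            all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
                0.8 * (centers[, 3] + r))) {
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place a non-melanoma nucleus within ",
             spec$max_tries, " tries; reduce n_nonmel or the radii")
      centers <- rbind(centers, c(cx, cy, r))
      q <- runif(1, spec$nonmel_axis_ratio[1], spec$nonmel_axis_ratio[2])
      theta <- runif(1, 0, pi)
      inside <- paint_ellipse(S, cx, cy, r, q, theta)
      col <- spec$nonmel_color + runif(3, -spec$color_jitter, spec$color_jitter)
      for (c in 1:3) {
        ch <- img[, , c]; ch[inside] <- col[c]; img[, , c] <- ch
      }
      lab[inside] <- 2L
    }

    # melanoma nuclei: one Gaussian cluster, painted over non-melanoma
    ccx <- runif(1, 0.25 * S, 0.75 * S)
    ccy <- runif(1, 0.25 * S, 0.75 * S)
    for (i in seq_len(spec$n_mel)) {
      r <- runif(1, spec$mel_radius[1], spec$mel_radius[2])
      cx <- min(max(rnorm(1, ccx, spec$cluster_sd), 1 + r), S - r)
      cy <- min(max(rnorm(1, ccy, spec$cluster_sd), 1 + r), S - r)
      q <- runif(1, spec$mel_axis_ratio[1], spec$mel_axis_ratio[2])
      theta <- runif(1, 0, pi)
      inside <- paint_ellipse(S, cx, cy, r, q, theta)
      col <- spec$mel_color + runif(3, -spec$color_jitter, spec$color_jitter)
      for (c in 1:3) {
        ch <- img[, , c]; ch[inside] <- col[c]; img[, , c] <- ch
      }
      lab[inside] <- 1L
    }

    img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
    img <- round(pmin(pmax(img, 0), 255))  # pmax(img, .) keeps the dim attribute
    structure(list(image = img, truth = lab, spec = spec, seed = seed),
              class = "labeled_sample")
  })
}

#' @export
print.labeled_sample <- function(x, ...) {
  f <- tabulate(x$truth, 3) / length(x$truth)
  cat("Synthetic H&E tile,", x$spec$tile, "x", x$spec$tile,
      "(seed", paste0(x$seed, ")"), "\n")
  cat(sprintf("  class fractions: melanoma %.3f, non-melanoma %.3f, background %.3f\n",
              f[1], f[2], f[3]))
  invisible(x)
}

#' Generate a synthetic dataset with a train/test/validation split
#'
#' Draws `n` tiles with disjoint derived seeds and assigns them to splits
#' by the given fractions (default 70/15/15).  With `dir` set, images and
#' truth maps are written as paired PNGs along with a YAML manifest that
#' [read_dataset()] round-trips.
#'
#' @param spec a [synth_spec].
#' @param n number of samples.
#' @param split named fractions for train/test/validation (must sum to 1).
#' @param seed master seed; per-sample seeds are derived from it.
#' @param dir optional output directory (created if missing).
#' @return an object of class `synth_dataset`: list with `samples`,
#'   `split` (factor), `spec`, `seed` and, when written, `dir` and
#'   `manifest`.
#' @export
generate_dataset <- function(spec = synth_spec(), n = 100,
                             split = c(train = 0.7, test = 0.15, val = 0.15),
                             seed = 1L, dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"), n >= 1)
  if (abs(sum(split) - 1) > 1e-9) stop("split fractions must sum to 1")
  if (n < sum(split > 0))
    stop("need at least one sample per nonzero split fraction")
  counts <- diff(c(0, round(cumsum(split) * n)))
  seeds <- (as.numeric(seed) + 104729 * seq_len(n)) %% 2147483647
  samples <- lapply(seeds, function(s) generate_sample(spec, as.integer(s)))
  fsplit <- factor(rep(names(split), counts), levels = names(split))
  ds <- structure(list(samples = samples, split = fsplit, spec = spec,
                       seed = seed),
                  class = "synth_dataset")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    entries <- vector("list", n)
    for (i in seq_len(n)) {
      img_f <- sprintf("img_%04d.png", i)
      msk_f <- sprintf("mask_%04d.png", i)
      write_image(samples[[i]]$image, file.path(dir, img_f))
      write_label_map(samples[[i]]$truth, file.path(dir, msk_f))
      entries[[i]] <- list(image = img_f, mask = msk_f,
                           split = as.character(fsplit[i]),
                           seed = as.integer(seeds[i]))
    }
    manifest <- list(n = n, seed = seed, spec = unclass(spec),
                     samples = entries)
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
    ds$dir <- dir
    ds$manifest <- file.path(dir, "manifest.yaml")
  }
  ds
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("Synthetic dataset:", length(x$samples), "tiles of",
      x$spec$tile, "x", x$spec$tile, "\n")
  print(table(x$split))
  invisible(x)
}

#' Subset the samples of one split
#'
#' @param ds a `synth_dataset`.
#' @param which split name (`"train"`, `"test"` or `"val"`).
#' @return list of `labeled_sample` objects.
#' @export
split_samples <- function(ds, which = "train") {
  stopifnot(inherits(ds, "synth_dataset"))
  ds$samples[ds$split == which]
}

#' Read a written synthetic dataset back from its manifest
#'
#' @param dir directory containing `manifest.yaml` (or a path to the
#'   manifest itself).
#' @return a `synth_dataset` (images and truth maps re-read from the
#'   PNGs).
#' @export
read_dataset <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "manifest.yaml") else dir
  man <- yaml::read_yaml(path)
  base <- dirname(path)
  spec <- do.call(synth_spec, man$spec[setdiff(names(man$spec), character())])
  samples <- lapply(man$samples, function(e) {
    structure(list(image = read_image(file.path(base, e$image)),
                   truth = read_label_map(file.path(base, e$mask)),
                   spec = spec, seed = e$seed),
              class = "labeled_sample")
  })
  fsplit <- factor(vapply(man$samples, `[[`, "", "split"),
                   levels = c("train", "test", "val"))
  structure(list(samples = samples, split = fsplit, spec = spec,
                 seed = man$seed, dir = base, manifest = path),
            class = "synth_dataset")
}
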