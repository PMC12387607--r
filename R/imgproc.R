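# Colour normalization, edge-enhanced view synthesis and exact quarter-turn
# rotations for the five-view test-time augmentation set.

#' Pooled per-channel statistics of a set of RGB images
#'
#' Computes the mean and population standard deviation of every channel,
#' pooling all pixels of all images in the collection.  These "global"
#' statistics are intended to be computed once over the training split and
#' reused to normalize both training and test images, so that the two are
#' on the same scale.
#'
#' @param images a single RGB image (`H x W x 3` array, values in 0..255) or
#'   a list of such arrays.
#' @param source optional identifier of the image set (stored for
#'   provenance).
#' @return an object of class `channel_stats`: a list with `mu` and `delta`
#'   (numeric length-3 vectors, intensity units) and `source`.
#' @examples
#' img <- array(100, dim = c(4, 4, 3))
#' channel_stats(img)$mu
#' @export
channel_stats <- function(images, source = NA_character_) {
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  if (!is.list(images) || length(images) == 0L)
    stop("'images' must be a non-empty list of H x W x 3 arrays")
  s <- s2 <- numeric(3)
  n <- 0
  for (img in images) {
    stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
    for (c in 1:3) {
      ch <- img[, , c]
      s[c] <- s[c] + sum(ch)
      s2[c] <- s2[c] + sum(ch^2)
    }
    n <- n + prod(dim(img)[1:2])
  }
  mu <- s / n
  delta <- sqrt(pmax(0, s2 / n - mu^2))  # population sd
  structure(list(mu = mu, delta = delta, source = source, n_pixels = n),
            class = "channel_stats")
}

#' @export
print.channel_stats <- function(x, ...) {
  cat("Channel statistics (", x$n_pixels, " pixels pooled",
      if (!is.na(x$source)) paste0(", source: ", x$source), ")\n", sep = "")
  m <- rbind(mu = x$mu, delta = x$delta)
  colnames(m) <- c("R", "G", "B")
  print(round(m, 3))
  invisible(x)
}

#' Z-score normalize an RGB image by channel statistics
#'
#' Each channel is centred by its global mean and divided by its global
#' standard deviation, `(x - mu) / max(delta, eps)`.  The `eps` floor keeps
#' degenerate constant channels finite.
#'
#' @param x RGB image, `H x W x 3` array.
#' @param stats a [channel_stats] object (typically of the training split).
#' @param eps small positive floor for the standard deviation.
#' @return `H x W x 3` array of dimensionless z-scores with attribute
#'   `"stats"` carrying the statistics used.
#' @seealso [denormalize_image()] for the exact inverse.
#' @export
normalize_image <- function(x, stats, eps = 1e-8) {
  stopifnot(inherits(stats, "channel_stats"), length(dim(x)) == 3L,
            dim(x)[3] == 3L, eps > 0)
  out <- x
  d <- pmax(stats$delta, eps)
  for (c in 1:3) out[, , c] <- (x[, , c] - stats$mu[c]) / d[c]
  attr(out, "stats") <- stats
  out
}

#' Invert z-score normalization
#'
#' @param z normalized image as returned by [normalize_image()].
#' @param stats the statistics used to normalize; defaults to the ones
#'   attached to `z`.
#' @param eps the same floor passed to [normalize_image()].
#' @return the reconstructed image (`values * delta + mu`).
#' @export
denormalize_image <- function(z, stats = attr(z, "stats"), eps = 1e-8) {
  stopifnot(inherits(stats, "channel_stats"))
  out <- z
  d <- pmax(stats$delta, eps)
  for (c in 1:3) out[, , c] <- z[, , c] * d[c] + stats$mu[c]
  attr(out, "stats") <- NULL
  out
}

#' Parameters of the edge-enhancement step
#'
#' The enhanced view of a tile is `clip(x * h + alpha * edges, 0, 255)`,
#' where `h` is a 3x3 Gaussian low-pass kernel applied per channel and
#' `edges` is a binary Canny edge mask computed on the luminance.  The
#' kernel defaults to the binomial approximation `(1,2,1) x (1,2,1) / 16`;
#' the edge boost defaults to `alpha = 20` intensity units.
#'
#' @param alpha edge boost added at edge pixels, intensity units (>= 0).
#' @param kernel 3x3 (or any odd-sized) nonnegative smoothing kernel summing
#'   to 1.
#' @param sigma Gaussian smoothing scale used inside the Canny detector.
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   gradient magnitude (`0 < low <= high <= 1`).
#' @return an object of class `enhance_params`.
#' @export
enhance_params <- function(alpha = 20,
                           kernel = outer(c(1, 2, 1), c(1, 2, 1)) / 16,
                           sigma = 1.0, low = 0.10, high = 0.20) {
  kernel <- as.matrix(kernel)
  if (any(kernel < 0) || abs(sum(kernel) - 1) > 1e-9)
    stop("smoothing kernel must be nonnegative and sum to 1")
  if (alpha < 0) stop("alpha must be >= 0")
  if (!(low > 0 && low <= high && high <= 1))
    stop("need 0 < low <= high <= 1 for the hysteresis fractions")
  structure(list(alpha = alpha, kernel = kernel, sigma = sigma,
                 low = low, high = high),
            class = "enhance_params")
}

# Rec. 601 luminance of an 8-bit RGB array
luminance <- function(x) {
  0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
}

#' Binary Canny edge mask of an RGB image
#'
#' Edges are detected on the Rec. 601 luminance
#' (`0.299 R + 0.587 G + 0.114 B`): Gaussian smoothing at `params$sigma`,
#' Sobel gradients, non-maximum suppression with the gradient direction
#' quantized to four bins, then hysteresis with thresholds
#' `params$low`/`params$high` times the maximum gradient magnitude and
#' 8-connected linking.
#'
#' @param x RGB image, `H x W x 3` array.
#' @param params an [enhance_params] object.
#' @return `H x W` integer matrix with values in `{0, 1}` (1 = edge).
#' @export
detect_edges <- function(x, params = enhance_params()) {
  stopifnot(inherits(params, "enhance_params"), length(dim(x)) == 3L)
  cpp_canny(luminance(x), params$sigma, params$low, params$high)
}

#' Edge-enhanced view of an RGB image
#'
#' Computes `clip(x * h + alpha * edges, 0, 255)`: each channel is smoothed
#' by the low-pass kernel `h` (symmetric/mirror boundary padding), then the
#' Canny edge mask (broadcast to all three channels) is boosted by `alpha`,
#' and the result is clipped to the 8-bit range.  On a constant image the
#' output equals the input because the kernel sums to 1 and there are no
#' edges.
#'
#' @inheritParams detect_edges
#' @return `H x W x 3` array with values in `[0, 255]`.
#' @export
enhance_image <- function(x, params = enhance_params()) {
  stopifnot(inherits(params, "enhance_params"))
  edges <- detect_edges(x, params)
  out <- x
  for (c in 1:3) {
    sm <- cpp_filter2_reflect(x[, , c], params$kernel)
    out[, , c] <- pmin(255, pmax(0, sm + params$alpha * edges))
  }
  out
}

#' Rotate an image-like array clockwise by quarter turns
#'
#' Works on 2D matrices (label maps, masks) and 3D arrays (RGB images,
#' probability maps); channel values are untouched.  One clockwise quarter
#' turn maps pixel `(m, n)` of an `M x N` input to `(n, M + 1 - m)` (1-based).
#' Four turns are the identity.
#'
#' @param x matrix or 3D array.
#' @param quarter_turns integer in `0:3` (values outside are reduced mod 4).
#' @return the rotated array; for odd turn counts the spatial dims are
#'   transposed.
#' @export
rotate_cw <- function(x, quarter_turns) {
  stopifnot(quarter_turns == as.integer(quarter_turns))
  q <- as.integer(quarter_turns) %% 4L
  if (q == 0L) return(x)
  rot1 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  f <- function(m) { for (i in seq_len(q)) m <- rot1(m); m }
  if (is.matrix(x)) return(f(x))
  stopifnot(length(dim(x)) == 3L)
  d <- dim(x)
  newd <- if (q %% 2L == 1L) c(d[2], d[1], d[3]) else d
  out <- array(x[1], dim = newd)
  for (c in seq_len(d[3])) out[, , c] <- f(x[, , c])
  out
}

#' Build the five-view test-time augmentation set
#'
#' The fixed view order is: original, 90, 180 and 270 degrees clockwise,
#' and the edge-enhanced image.  Each view stores the inverse geometric
#' transform (counter-rotation for the rotated views, identity for the
#' original and enhanced views) used to map per-view predictions back to
#' the original pixel grid.
#'
#' @param x RGB image, `H x W x 3` array.
#' @param params an [enhance_params] object for the enhanced view.
#' @return an object of class `augmentation_set`: list with `views` (list of
#'   5 arrays), `turns` (forward clockwise quarter turns applied:
#'   `c(0, 1, 2, 3, 0)`) and `inverse_turns` (clockwise quarter turns that
#'   undo each view: `c(0, 3, 2, 1, 0)`).
#' @export
make_augmentation_set <- function(x, params = enhance_params()) {
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == 3L)
  turns <- c(0L, 1L, 2L, 3L, 0L)
  views <- list(x, rotate_cw(x, 1), rotate_cw(x, 2), rotate_cw(x, 3),
                enhance_image(x, params))
  structure(list(views = views, turns = turns,
                 inverse_turns = (4L - turns) %% 4L,
                 names = c("original", "rot90", "rot180", "rot270", "enhanced")),
            class = "augmentation_set")
}

#' @export
print.augmentation_set <- function(x, ...) {
  d <- dim(x$views[[1]])
  cat("Augmentation set: 5 views of a", d[1], "x", d[2], "RGB tile\n")
  cat("  views:", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}
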