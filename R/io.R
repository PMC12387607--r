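# Reading and writing images, label maps and channel statistics.
# 8-bit RGB as PNG or TIFF; label maps and binary masks as single-channel
# PNG holding the raw integer codes (1/2/3 for class maps, 0/1 for masks);
# statistics as a small YAML record.

#' Read an 8-bit RGB image
#'
#' @param path PNG or TIFF file.
#' @return `H x W x 3` array with intensities in 0..255.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              png = png::readPNG(path),
              tif = , tiff = tiff::readTIFF(path),
              stop("unsupported image format: .", ext))
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), dim = c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  round(x * 255)
}

#' Write an 8-bit RGB image
#'
#' @param x `H x W x 3` array with intensities in 0..255.
#' @param path output file; format chosen by extension (.png/.tif/.tiff).
#' @return the path, invisibly.
#' @export
write_image <- function(x, path) {
  stopifnot(length(dim(x)) == 3L, all(x >= 0), all(x <= 255))
  ext <- tolower(tools::file_ext(path))
  v <- x / 255
  switch(ext,
         png = png::writePNG(v, path),
         tif = , tiff = tiff::writeTIFF(v, path, bits.per.sample = 8L),
         stop("unsupported image format: .", ext))
  invisible(path)
}

#' Read an indexed label map or binary mask
#'
#' @param path single-channel PNG whose gray levels are the integer codes.
#' @return integer matrix.
#' @export
read_label_map <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  m <- round(x * 255)
  storage.mode(m) <- "integer"
  m
}

#' Write an indexed label map or binary mask
#'
#' @param m integer matrix (values 0..255, e.g. 1/2/3 class codes or a 0/1
#'   mask).
#' @param path output PNG.
#' @return the path, invisibly.
#' @export
write_label_map <- function(m, path) {
  stopifnot(is.matrix(m), all(m >= 0), all(m <= 255))
  png::writePNG(m / 255, path)
  invisible(path)
}

#' Render a class map in the conventional colours
#'
#' Class 1 (melanoma) red, class 2 (non-melanoma) green, class 3
#' (background) blue.
#'
#' @param cm `H x W` integer class map in 1..3.
#' @return `H x W x 3` RGB array, 0..255.
#' @export
render_class_map <- function(cm) {
  stopifnot(all(cm %in% 1:3))
  out <- array(0, dim = c(dim(cm), 3L))
  for (k in 1:3) out[, , k] <- (cm == k) * 255
  out
}

#' Write channel statistics to YAML
#'
#' @param stats a [channel_stats].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_channel_stats <- function(stats, path) {
  stopifnot(inherits(stats, "channel_stats"))
  yaml::write_yaml(list(mu = as.numeric(stats$mu),
                        delta = as.numeric(stats$delta),
                        source = as.character(stats$source),
                        n_pixels = stats$n_pixels),
                   path)
  invisible(path)
}

#' Read channel statistics from YAML
#'
#' @param path file written by [write_channel_stats()].
#' @return a [channel_stats].
#' @export
read_channel_stats <- function(path) {
  y <- yaml::read_yaml(path)
  structure(list(mu = as.numeric(y$mu), delta = as.numeric(y$delta),
                 source = y$source, n_pixels = y$n_pixels),
            class = "channel_stats")
}
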