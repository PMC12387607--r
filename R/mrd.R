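# Melanoma region detection: morphological post-processing of the class
# map (dilation, hole filling, erosion, minimum-area threshold) and region
# extraction/visualization utilities.

#' Morphology parameters for melanoma region detection
#'
#' @param dilate_radius,erode_radius disk structuring-element radii in
#'   pixels (>= 1).
#' @param min_area minimum connected-component area in pixels kept after
#'   erosion (>= 0); 8-connectivity.
#' @return an object of class `morphology_params`.
#' @export
morphology_params <- function(dilate_radius = 2, erode_radius = 2,
                              min_area = 100) {
  stopifnot(dilate_radius >= 1, erode_radius >= 1, min_area >= 0)
  structure(list(dilate_radius = as.integer(dilate_radius),
                 erode_radius = as.integer(erode_radius),
                 min_area = as.integer(min_area)),
            class = "morphology_params")
}

#' Disk structuring element
#'
#' Logical `(2r+1) x (2r+1)` matrix with `TRUE` where
#' `dx^2 + dy^2 <= r^2`.
#'
#' @param r radius in pixels.
#' @return logical matrix.
#' @export
disk_se <- function(r) {
  stopifnot(r >= 0)
  d <- -r:r
  outer(d, d, function(i, j) i^2 + j^2 <= r^2)
}

#' Binary melanoma mask of a class map
#'
#' @param cm `H x W` integer class map with values in 1..3.
#' @return `H x W` integer matrix, 1 exactly where the class is 1
#'   (melanoma), before any morphology.
#' @export
melanoma_mask <- function(cm) {
  stopifnot(is.matrix(cm), all(cm %in% 1:3))
  m <- matrix(0L, nrow(cm), ncol(cm))
  m[cm == 1L] <- 1L
  m
}

#' Morphological cleanup of a binary region mask
#'
#' Applies, in order: binary dilation with a disk structuring element, hole
#' filling (background regions not 8-connected to the image border become
#' foreground), binary erosion with a disk, and removal of 8-connected
#' components smaller than `min_area` pixels.  Pixels outside the image are
#' treated as background, so erosion shrinks regions touching the border.
#'
#' @param mask `H x W` binary (0/1) integer matrix.
#' @param params a [morphology_params].
#' @return cleaned binary mask.
#' @export
apply_morphology <- function(mask, params = morphology_params()) {
  stopifnot(inherits(params, "morphology_params"), is.matrix(mask))
  storage.mode(mask) <- "integer"
  m <- cpp_dilate(mask, disk_se(params$dilate_radius))
  m <- cpp_fill_holes(m)
  m <- cpp_erode(m, disk_se(params$erode_radius))
  if (params$min_area > 0) {
    lab <- cpp_label(m)
    if (max(lab) > 0) {
      areas <- tabulate(lab[lab > 0], nbins = max(lab))
      drop <- which(areas < params$min_area)
      if (length(drop)) m[lab %in% drop] <- 0L
    }
  }
  m
}

#' Table of connected components in a binary mask
#'
#' @param mask binary (0/1) matrix.
#' @return data.frame with one row per 8-connected component: `id`, `area`
#'   (pixels) and bounding box (`rmin`, `rmax`, `cmin`, `cmax`).
#' @export
region_table <- function(mask) {
  storage.mode(mask) <- "integer"
  lab <- cpp_label(mask)
  n <- max(lab)
  if (n == 0)
    return(data.frame(id = integer(), area = integer(), rmin = integer(),
                      rmax = integer(), cmin = integer(), cmax = integer()))
  do.call(rbind, lapply(seq_len(n), function(i) {
    w <- which(lab == i, arr.ind = TRUE)
    data.frame(id = i, area = nrow(w), rmin = min(w[, 1]), rmax = max(w[, 1]),
               cmin = min(w[, 2]), cmax = max(w[, 2]))
  }))
}

#' Extract masked regions from an image
#'
#' @param x RGB image, `H x W x 3`.
#' @param mask binary (0/1) matrix of matching spatial dims.
#' @return image with pixels outside the mask set to 0 and pixels inside
#'   copied verbatim.
#' @export
extract_regions <- function(x, mask) {
  stopifnot(length(dim(x)) == 3L)
  if (!all(dim(x)[1:2] == dim(mask)))
    stop("image and mask dims differ")
  out <- x
  for (c in seq_len(dim(x)[3])) out[, , c] <- x[, , c] * (mask == 1)
  out
}

#' Pixelwise agreement overlay of two binary masks
#'
#' Renders the four confusion outcomes in the conventional colours:
#' true positives white, true negatives black, false positives green,
#' false negatives purple.
#'
#' @param pred,truth binary (0/1) matrices of equal dims.
#' @return `H x W x 3` RGB array with values in 0..255.
#' @export
overlay_eval <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("mask dims differ")
  cols <- rbind(tp = c(255, 255, 255), tn = c(0, 0, 0),
                fp = c(0, 255, 0), fn = c(128, 0, 128))
  out <- array(0, dim = c(dim(pred), 3L))
  idx <- list(tp = pred == 1 & truth == 1, tn = pred == 0 & truth == 0,
              fp = pred == 1 & truth == 0, fn = pred == 0 & truth == 1)
  for (k in names(idx))
    for (c in 1:3) {
      ch <- out[, , c]
      ch[idx[[k]]] <- cols[k, c]
      out[, , c] <- ch
    }
  out
}
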