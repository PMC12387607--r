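# 64x64 tiling and stitching.  Large tiles are mirror-padded up to a
# multiple of the patch size, cut into non-overlapping row-major blocks for
# the network, and the stitched output is cropped back to the original dims.

mirror_idx <- function(i, n) {
  # symmetric padding index: 0 -> 1, -1 -> 2, n+1 -> n, ... (1-based)
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

#' Non-overlapping patch grid for an image
#'
#' @param h,w image height and width in pixels.
#' @param patch patch side length (default 64).
#' @return an object of class `patch_grid` with the padded dims and the
#'   row-major block origins.
#' @export
patch_grid <- function(h, w, patch = 64L) {
  stopifnot(h >= 1, w >= 1, patch >= 1)
  ph <- as.integer(ceiling(h / patch) * patch)
  pw <- as.integer(ceiling(w / patch) * patch)
  rows <- seq(1L, ph, by = patch)
  cols <- seq(1L, pw, by = patch)
  origins <- expand.grid(col = cols, row = rows)[, c("row", "col")]  # row-major
  structure(list(h = as.integer(h), w = as.integer(w), patch = as.integer(patch),
                 padded_h = ph, padded_w = pw, origins = origins),
            class = "patch_grid")
}

pad_mirror <- function(x, ph, pw) {
  d <- dim(x)
  ri <- mirror_idx(seq_len(ph), d[1])
  ci <- mirror_idx(seq_len(pw), d[2])
  if (length(d) == 2L) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
}

#' Cut an image into non-overlapping patches
#'
#' The image is mirror-padded to the grid's padded dims, then split into
#' row-major `patch x patch` blocks.  Works for 2D maps and 3D arrays.
#'
#' @param x matrix or `H x W x C` array.
#' @param grid a [patch_grid] for `dim(x)`; defaults to the 64-patch grid.
#' @return array of shape `patch x patch x C x n_patches` (C = 1 for
#'   matrix input).
#' @export
extract_patches <- function(x, grid = patch_grid(dim(x)[1], dim(x)[2])) {
  stopifnot(inherits(grid, "patch_grid"),
            dim(x)[1] == grid$h, dim(x)[2] == grid$w)
  is2d <- length(dim(x)) == 2L
  if (is2d) dim(x) <- c(dim(x), 1L)
  xp <- pad_mirror(x, grid$padded_h, grid$padded_w)
  p <- grid$patch
  n <- nrow(grid$origins)
  out <- array(0, dim = c(p, p, dim(x)[3], n))
  for (i in seq_len(n)) {
    r <- grid$origins$row[i]; c <- grid$origins$col[i]
    out[, , , i] <- xp[r:(r + p - 1L), c:(c + p - 1L), , drop = FALSE]
  }
  out
}

#' Reassemble patches into a full map
#'
#' Exact inverse of [extract_patches()] up to the crop of the mirror
#' padding; values are copied verbatim, so probability patches remain on
#' the simplex.
#'
#' @param patches array `patch x patch x C x n` as returned by
#'   [extract_patches()] (or a compatible prediction array).
#' @param grid the [patch_grid] the patches came from.
#' @return `H x W` matrix if `C == 1`, else `H x W x C` array, cropped to
#'   the original dims.
#' @export
stitch_patches <- function(patches, grid) {
  stopifnot(inherits(grid, "patch_grid"), length(dim(patches)) == 4L)
  p <- grid$patch
  n <- nrow(grid$origins)
  if (dim(patches)[4] != n)
    stop("patch count (", dim(patches)[4], ") does not match grid (", n, ")")
  ch <- dim(patches)[3]
  full <- array(0, dim = c(grid$padded_h, grid$padded_w, ch))
  for (i in seq_len(n)) {
    r <- grid$origins$row[i]; c <- grid$origins$col[i]
    full[r:(r + p - 1L), c:(c + p - 1L), ] <- patches[, , , i]
  }
  out <- full[seq_len(grid$h), seq_len(grid$w), , drop = FALSE]
  if (ch == 1L) dim(out) <- dim(out)[1:2]
  out
}
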