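# Brute-force set-definition oracles for binary morphology, independent of
# the package's C++ implementation.  Conventions mirror the documented
# ones: pixels outside the image are background; hole filling and
# component labelling are 8-connected.

oracle_dilate <- function(mask, se) {
  H <- nrow(mask); W <- ncol(mask)
  r <- (nrow(se) - 1) / 2
  offs <- which(se, arr.ind = TRUE) - (r + 1)
  out <- matrix(0L, H, W)
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1]; dc <- offs[k, 2]
    sr <- max(1, 1 - dr):min(H, H - dr)
    sc <- max(1, 1 - dc):min(W, W - dc)
    out[sr + dr, sc + dc] <- out[sr + dr, sc + dc] | mask[sr, sc]
  }
  out * 1L
}

oracle_erode <- function(mask, se) {
  H <- nrow(mask); W <- ncol(mask)
  r <- (nrow(se) - 1) / 2
  offs <- which(se, arr.ind = TRUE) - (r + 1)
  out <- matrix(TRUE, H, W)
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1]; dc <- offs[k, 2]
    shifted <- matrix(FALSE, H, W)
    sr <- max(1, 1 - dr):min(H, H - dr)
    sc <- max(1, 1 - dc):min(W, W - dc)
    shifted[sr, sc] <- mask[sr + dr, sc + dc] == 1
    out <- out & shifted
  }
  out * 1L
}

# breadth-first search over a logical "open" grid from seed pixels,
# 8-connected; returns the reached set
bfs8 <- function(open, seed_r, seed_c) {
  H <- nrow(open); W <- ncol(open)
  reach <- matrix(FALSE, H, W)
  ok <- open[cbind(seed_r, seed_c)] & !reach[cbind(seed_r, seed_c)]
  qr <- seed_r[ok]; qc <- seed_c[ok]
  reach[cbind(qr, qc)] <- TRUE
  head <- 1L
  while (head <= length(qr)) {
    r <- qr[head]; c <- qc[head]; head <- head + 1L
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
          open[rr, cc] && !reach[rr, cc]) {
        reach[rr, cc] <- TRUE
        qr <- c(qr, rr); qc <- c(qc, cc)
      }
    }
  }
  reach
}

oracle_fill <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seed_r <- c(seq_len(H), seq_len(H), rep(1L, W), rep(H, W))
  seed_c <- c(rep(1L, H), rep(W, H), seq_len(W), seq_len(W))
  reach <- bfs8(mask == 0, seed_r, seed_c)
  (mask == 1 | !reach) * 1L
}

oracle_label <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  todo <- which(mask == 1 & lab == 0L, arr.ind = TRUE)
  while (nrow(todo) > 0) {
    nxt <- nxt + 1L
    comp <- bfs8(mask == 1, todo[1, 1], todo[1, 2])
    lab[comp] <- nxt
    todo <- which(mask == 1 & lab == 0L, arr.ind = TRUE)
  }
  lab
}

oracle_area_filter <- function(mask, min_area) {
  lab <- oracle_label(mask)
  if (max(lab) == 0) return(mask)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  mask[lab %in% which(areas < min_area)] <- 0L
  mask
}

oracle_morphology <- function(mask, params) {
  m <- oracle_dilate(mask, disk_se(params$dilate_radius))
  m <- oracle_fill(m)
  m <- oracle_erode(m, disk_se(params$erode_radius))
  if (params$min_area > 0) m <- oracle_area_filter(m, params$min_area)
  m
}

# random test masks: mixture of salt noise and smooth blobs
random_mask <- function(h, w, kind = c("noise", "blobs"), p = 0.3) {
  kind <- match.arg(kind)
  if (kind == "noise") {
    matrix(rbinom(h * w, 1, p), h, w)
  } else {
    z <- matrix(rnorm(h * w), h, w)
    z <- nucseg:::cpp_gauss_smooth(z, 2)
    (z > quantile(z, 1 - p)) * 1L
  }
}
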