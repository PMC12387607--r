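# Combining per-view probability maps: probability averaging and majority
# voting, after every view has been mapped back to the original pixel grid.

#' Bundle per-view probability maps into a stack
#'
#' All maps must already be in the original image frame (inverse geometric
#' transforms applied) and share spatial dims; each per-pixel probability
#' triple must be (approximately) on the simplex.
#'
#' @param maps list of `H x W x 3` probability arrays.
#' @param views optional character vector of view names.
#' @return an object of class `prob_stack`.
#' @export
prob_stack <- function(maps, views = NULL) {
  stopifnot(is.list(maps), length(maps) >= 1)
  d <- dim(maps[[1]])
  for (m in maps) {
    if (!identical(dim(m), d))
      stop("all probability maps must share dims")
    if (length(d) != 3L || d[3] != 3L)
      stop("probability maps must be H x W x 3")
  }
  s <- maps[[1]][, , 1] + maps[[1]][, , 2] + maps[[1]][, , 3]
  if (max(abs(s - 1)) > 1e-6)
    stop("per-pixel probabilities must sum to 1")
  if (is.null(views)) views <- paste0("view", seq_along(maps))
  structure(list(maps = maps, views = views), class = "prob_stack")
}

#' @export
print.prob_stack <- function(x, ...) {
  d <- dim(x$maps[[1]])
  cat("Probability stack:", length(x$maps), "views of", d[1], "x", d[2],
      "x 3 maps\n  views:", paste(x$views, collapse = ", "), "\n")
  invisible(x)
}

#' Averaging ensemble
#'
#' Averages the per-view probability maps pixelwise and assigns each pixel
#' the class with maximal mean probability (argmax ties broken by the
#' lowest class index).
#'
#' @param stack a [prob_stack].
#' @return list with `pav` (the averaged `H x W x 3` probability map) and
#'   `class_map` (`H x W` integer matrix in 1..3).
#' @export
average_ensemble <- function(stack) {
  stopifnot(inherits(stack, "prob_stack"))
  pav <- Reduce(`+`, stack$maps) / length(stack$maps)
  list(pav = pav, class_map = argmax_classes(pav))
}

#' Voting ensemble
#'
#' Each view votes with its per-pixel argmax class; the modal class wins.
#' Pixels where the vote counts tie fall back to the averaging ensemble
#' (argmax of the mean probability vector at that pixel).
#'
#' @param stack a [prob_stack].
#' @return `H x W` integer class matrix in 1..3.
#' @export
vote_ensemble <- function(stack) {
  stopifnot(inherits(stack, "prob_stack"))
  votes <- lapply(stack$maps, argmax_classes)
  d <- dim(votes[[1]])
  counts <- array(0L, dim = c(d, 3L))
  for (v in votes)
    for (k in 1:3) counts[, , k] <- counts[, , k] + (v == k)
  top <- pmax(counts[, , 1], counts[, , 2], counts[, , 3])
  tie <- (counts[, , 1] == top) + (counts[, , 2] == top) +
    (counts[, , 3] == top) > 1L
  out <- argmax_classes(counts)  # modal class, ties to lowest index for now
  if (any(tie)) {
    avg <- average_ensemble(stack)$class_map
    out[tie] <- avg[tie]
  }
  out
}

#' Test-time augmentation inference
#'
#' Builds the five-view augmentation set of `x` (original, three clockwise
#' rotations, edge-enhanced), predicts class probabilities for every view,
#' applies each view's inverse transform so all maps live on the original
#' pixel grid, and combines them by probability averaging or majority
#' voting.  With `views = 3` only the original and the 90/270-degree
#' rotations participate; with `views = 1` or `mode = "none"` this reduces
#' to a plain single pass.
#'
#' @param model a predictor with a [predict_probabilities()] method.
#' @param x raw RGB image (`H x W x 3`, 0..255).
#' @param params [enhance_params()] used for the enhanced view.
#' @param mode `"average"`, `"vote"` or `"none"`.
#' @param views 5, 3 or 1.
#' @return `H x W` integer class matrix in 1..3.  For `mode = "average"`
#'   the averaged probability map is attached as attribute `"pav"`.
#' @export
run_tta_inference <- function(model, x, params = enhance_params(),
                              mode = c("average", "vote", "none"),
                              views = 5) {
  mode <- match.arg(mode)
  stopifnot(views %in% c(1, 3, 5))
  if (mode == "none" || views == 1) {
    p <- predict_probabilities(model, x)
    cm <- argmax_classes(p)
    attr(cm, "pav") <- p
    return(cm)
  }
  aug <- make_augmentation_set(x, params)
  keep <- if (views == 5) 1:5 else c(1L, 2L, 4L)  # original, 90, 270
  maps <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    v <- keep[i]
    pv <- predict_probabilities(model, aug$views[[v]])
    maps[[i]] <- rotate_cw(pv, aug$inverse_turns[v])
  }
  stack <- prob_stack(maps, views = aug$names[keep])
  if (mode == "average") {
    res <- average_ensemble(stack)
    cm <- res$class_map
    attr(cm, "pav") <- res$pav
    cm
  } else {
    vote_ensemble(stack)
  }
}

#' Per-pixel nearest-colour rule classifier
#'
#' A deterministic stand-in predictor that assigns each pixel the class of
#' the nearest reference colour (squared Euclidean distance in RGB) and
#' emits one-hot probabilities.  Because the rule is purely per-pixel it is
#' exactly rotation-equivariant, which makes it the reference oracle for
#' checking the coordinate bookkeeping of the test-time augmentation
#' ensemble.
#'
#' @param centers 3 x 3 numeric matrix of reference colours, one row per
#'   class (melanoma, non-melanoma, background), columns R, G, B.
#' @return an object of class `pixel_rule` usable with
#'   [predict_probabilities()] and [run_tta_inference()].
#' @export
color_rule_classifier <- function(centers = rbind(melanoma = c(70, 50, 120),
                                                  non_melanoma = c(95, 70, 150),
                                                  background = c(230, 185, 205))) {
  centers <- as.matrix(centers)
  stopifnot(nrow(centers) == 3, ncol(centers) == 3)
  structure(list(centers = centers), class = "pixel_rule")
}

#' @rdname predict_probabilities
#' @export
predict_probabilities.pixel_rule <- function(model, x, ...) {
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == 3L)
  d <- dim(x)
  dist <- array(0, dim = c(d[1], d[2], 3L))
  for (k in 1:3)
    dist[, , k] <- (x[, , 1] - model$centers[k, 1])^2 +
      (x[, , 2] - model$centers[k, 2])^2 +
      (x[, , 3] - model$centers[k, 3])^2
  cls <- argmax_classes(-dist)
  p <- array(0, dim = c(d[1], d[2], 3L))
  for (k in 1:3) p[, , k] <- (cls == k) * 1
  p
}
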