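# Model fitting and prediction.

#' Fit the dual-path pixel classifier
#'
#' Trains the dual-path convolutional network on (image, label-map) pairs
#' with Adam on class-weighted softmax cross-entropy.  Images are z-score
#' normalized by pooled training-split channel statistics (computed here
#' unless supplied); labels use 1 = melanoma nuclei, 2 = non-melanoma
#' nuclei, 3 = background.  Training is deterministic for a fixed seed on
#' one machine.
#'
#' @param x training images: `H x W x 3 x N` array of raw 8-bit intensities
#'   (0..255), or a list of `labeled_sample` objects from
#'   [generate_sample()] (in which case `y` is taken from them).  `H` and
#'   `W` must be multiples of 16 (the coarse path halves the resolution
#'   four times).
#' @param y training labels: `H x W x N` integer array with values 1..3.
#' @param config a [dpnet_config].
#' @param stats optional [channel_stats] to normalize by; computed from `x`
#'   when `NULL`.
#' @param epochs,lr,batch_size,seed training schedule: Adam learning rate
#'   `lr`, minibatch size, RNG seed for weight initialization and
#'   shuffling.
#' @param class_weights length-3 loss weights; by default inverse class
#'   frequency on the training labels, `n_total / (3 * n_c)` (absent
#'   classes get weight 0).
#' @param validation optional `list(x =, y =)` held-out set (same formats);
#'   when given, the per-epoch history records the nuclei-binarized Dice
#'   (classes 1+2 vs 3) on it.
#' @param verbose print per-epoch progress.
#' @return an object of class `dpnet`: the configuration, trained weights,
#'   normalization statistics, training history and control settings.
#'   Methods: [predict.dpnet()], `print`, `summary`, `plot`,
#'   [count_parameters()].
#' @export
fit_dpnet <- function(x, y = NULL, config = dpnet_config(), stats = NULL,
                      epochs = 50L, lr = 1e-3, batch_size = 32L, seed = 1L,
                      class_weights = NULL, validation = NULL,
                      verbose = FALSE) {
  xy <- as_xy(x, y)
  x <- xy$x; y <- xy$y
  if (dim(x)[4] == 0L || is.null(y)) stop("empty training set")
  check_divisible(dim(x)[1], dim(x)[2])
  if (is.null(stats)) {
    imgs <- lapply(seq_len(dim(x)[4]), function(i) x[, , , i, drop = TRUE])
    stats <- channel_stats(imgs, source = "training split")
  }
  xn <- normalize_batch(x, stats)
  if (is.null(class_weights)) {
    tab <- tabulate(y, nbins = config$classes)
    class_weights <- ifelse(tab > 0, sum(tab) / (config$classes * tab), 0)
  }
  stopifnot(length(class_weights) == config$classes)

  val <- NULL
  if (!is.null(validation)) {
    vxy <- as_xy(validation$x, validation$y)
    val <- list(x = normalize_batch(vxy$x, stats), y = vxy$y)
  }

  net <- compile_network(config)
  w0 <- cpp_init_weights(net$nodes, config$in_channels, as.integer(seed))
  opts <- list(epochs = as.integer(epochs), lr = lr,
               batch_size = as.integer(batch_size), seed = as.integer(seed),
               class_weights = as.numeric(class_weights))
  res <- cpp_train(net$nodes, w0, xn, as.integer(y), opts,
                   if (is.null(val)) NULL else val$x,
                   if (is.null(val)) NULL else as.integer(val$y))
  history <- data.frame(epoch = seq_len(epochs), loss = res$loss,
                        val_dice = res$val_dice)
  if (verbose) {
    msg <- sprintf("epoch %d  loss %.4f%s", history$epoch, history$loss,
                   ifelse(is.na(history$val_dice), "",
                          sprintf("  val Dice %.4f", history$val_dice)))
    cat(msg, sep = "\n")
  }
  structure(list(config = config, nodes = net$nodes, weights = res$weights,
                 stats = stats, history = history,
                 control = list(epochs = epochs, lr = lr,
                                batch_size = batch_size, seed = seed,
                                class_weights = class_weights),
                 classes = c("melanoma", "non_melanoma", "background")),
            class = "dpnet")
}

#' Build an untrained network
#'
#' Instantiates the dual-path classifier with freshly initialized weights
#' (He initialization, deterministic in `seed`) without training it.
#' Useful for architecture inspection ([count_parameters()],
#' [network_layer_table()]) and as the starting point of custom training
#' loops.  Prediction requires [channel_stats] (pass some via `stats` or
#' fit the model instead).
#'
#' @param config a [dpnet_config].
#' @param seed RNG seed for the weight initialization.
#' @param stats optional [channel_stats] for prediction.
#' @return an untrained `dpnet` object.
#' @export
build_network <- function(config = dpnet_config(), seed = 1L, stats = NULL) {
  net <- compile_network(config)
  w <- cpp_init_weights(net$nodes, config$in_channels, as.integer(seed))
  structure(list(config = config, nodes = net$nodes, weights = w,
                 stats = stats,
                 history = data.frame(epoch = integer(), loss = numeric(),
                                      val_dice = numeric()),
                 control = list(seed = seed),
                 classes = c("melanoma", "non_melanoma", "background")),
            class = "dpnet")
}

#' Save / load a fitted model
#'
#' The checkpoint is a standard R serialization (RDS) of the model object;
#' alongside it a human-readable YAML sidecar (`<path>.yaml`) records the
#' architecture configuration and normalization statistics.
#'
#' @param model a `dpnet`.
#' @param path checkpoint file (e.g. `model.rds`).
#' @return `save_dpnet` the path invisibly; `load_dpnet` the model.
#' @export
save_dpnet <- function(model, path) {
  stopifnot(inherits(model, "dpnet"))
  saveRDS(model, path)
  side <- list(config = unclass(model$config),
               control = model$control,
               parameters = count_parameters(model))
  if (!is.null(model$stats))
    side$stats <- list(mu = as.numeric(model$stats$mu),
                       delta = as.numeric(model$stats$delta))
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_dpnet
#' @export
load_dpnet <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "dpnet"))
  model
}

# accept either (array, array) or a list of labeled samples
as_xy <- function(x, y) {
  if (is.list(x) && !is.array(x)) {
    stopifnot(length(x) > 0)
    d <- dim(x[[1]]$image)
    xa <- array(0, dim = c(d[1], d[2], 3L, length(x)))
    ya <- array(0L, dim = c(d[1], d[2], length(x)))
    for (i in seq_along(x)) {
      xa[, , , i] <- x[[i]]$image
      ya[, , i] <- x[[i]]$truth
    }
    return(list(x = xa, y = ya))
  }
  stopifnot(length(dim(x)) == 4L)
  list(x = x, y = y)
}

check_divisible <- function(h, w) {
  if (h %% 16L != 0L || w %% 16L != 0L)
    stop("input dims (", h, " x ", w, ") must be multiples of 16: the ",
         "coarse path downsamples 2x at each of its 4 levels")
}

normalize_batch <- function(x, stats, eps = 1e-8) {
  d <- pmax(stats$delta, eps)
  out <- x
  for (c in 1:3) out[, , c, ] <- (x[, , c, ] - stats$mu[c]) / d[c]
  out
}

#' @export
print.dpnet <- function(x, ...) {
  cat("Dual-path pixel classifier (3-class H&E segmentation)\n")
  cat("  trainable parameters:",
      format(count_parameters(x), big.mark = ","), "\n")
  cat("  trained for", nrow(x$history), "epochs, final loss",
      sprintf("%.4f", tail(x$history$loss, 1)), "\n")
  vd <- tail(stats::na.omit(x$history$val_dice), 1)
  if (length(vd)) cat("  final validation Dice (nuclei vs background):",
                      sprintf("%.4f", vd), "\n")
  invisible(x)
}

#' @export
summary.dpnet <- function(object, ...) {
  tab <- network_layer_table(object$config)
  cat("Layer table:\n")
  print(tab, row.names = FALSE)
  cat("\nTotal trainable parameters:",
      format(sum(tab$params), big.mark = ","), "\n")
  cat("\nTraining control:\n")
  str(object$control, give.head = FALSE)
  cat("\nHistory (last 5 epochs):\n")
  print(tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
plot.dpnet <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  if (any(!is.na(h$val_dice))) {
    graphics::par(new = TRUE)
    graphics::plot(h$epoch, h$val_dice, type = "l", lty = 2, axes = FALSE,
                   xlab = "", ylab = "", ylim = c(0, 1))
    graphics::axis(4)
    graphics::mtext("validation Dice", side = 4, line = 2)
  }
  invisible(x)
}

#' Per-pixel class probabilities for an image
#'
#' Generic used by the ensemble machinery: every predictor (the fitted
#' network, or a hand-built per-pixel rule) maps a raw RGB image to an
#' `H x W x 3` probability array whose per-pixel values sum to 1.
#'
#' @param model a predictor (e.g. a fitted `dpnet` or a
#'   [color_rule_classifier()]).
#' @param x raw RGB image, `H x W x 3`, intensities 0..255.  Any size: the
#'   image is normalized, mirror-padded and tiled into 64x64 blocks
#'   internally, and the stitched map is cropped back.
#' @param ... method-specific arguments.
#' @return `H x W x 3` probability array (classes: melanoma, non-melanoma,
#'   background).
#' @export
predict_probabilities <- function(model, x, ...) UseMethod("predict_probabilities")

#' @rdname predict_probabilities
#' @param chunk_size number of 64x64 patches run through the network per
#'   forward call (memory/speed trade-off).
#' @export
predict_probabilities.dpnet <- function(model, x, chunk_size = 16L, ...) {
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == 3L)
  if (is.null(model$stats))
    stop("model carries no channel statistics; fit it, or build it with ",
         "build_network(stats = ...)")
  grid <- patch_grid(dim(x)[1], dim(x)[2], 64L)
  patches <- extract_patches(x, grid)
  n <- dim(patches)[4]
  probs <- array(0, dim = c(64L, 64L, model$config$classes, n))
  for (s in seq(1L, n, by = chunk_size)) {
    e <- min(n, s + chunk_size - 1L)
    xb <- normalize_batch(patches[, , , s:e, drop = FALSE], model$stats)
    probs[, , , s:e] <- cpp_forward(model$nodes, model$weights, xb, TRUE)
  }
  stitch_patches(probs, grid)
}

#' Predict segmentation for an image
#'
#' @param object fitted `dpnet`.
#' @param x raw RGB image (`H x W x 3`, 0..255), any size.
#' @param type `"class"` for the 1/2/3 label map, `"prob"` for the
#'   probability array.
#' @param tta test-time augmentation mode: `"none"` (single pass),
#'   `"average"` (mean of per-view probabilities) or `"vote"` (per-pixel
#'   majority with averaging tie-break).
#' @param views number of augmented views when `tta != "none"`: 5 (all) or
#'   3 (original + 90 + 270 degrees).
#' @param params [enhance_params()] for the enhanced view.
#' @param ... unused.
#' @return label matrix (`type = "class"`) or probability array
#'   (`type = "prob"`; for `tta = "average"` the averaged map, otherwise
#'   the single-pass map).
#' @export
predict.dpnet <- function(object, x, type = c("class", "prob"),
                          tta = c("none", "average", "vote"), views = 5,
                          params = enhance_params(), ...) {
  type <- match.arg(type)
  tta <- match.arg(tta)
  if (tta == "none") {
    p <- predict_probabilities(object, x)
    if (type == "prob") return(p)
    return(argmax_classes(p))
  }
  cm <- run_tta_inference(object, x, params = params, mode = tta,
                          views = views)
  if (type == "class") return(cm)
  pav <- attr(cm, "pav")
  if (is.null(pav))
    stop("probability output is only available for tta = 'average'")
  pav
}

# argmax over the class axis, ties broken by lowest class index
argmax_classes <- function(p) {
  stopifnot(length(dim(p)) == 3L)
  m1 <- p[, , 1]; m2 <- p[, , 2]; m3 <- p[, , 3]
  out <- matrix(3L, nrow = dim(p)[1], ncol = dim(p)[2])
  out[m2 >= m3] <- 2L
  out[m1 >= m2 & m1 >= m3] <- 1L
  out
}
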