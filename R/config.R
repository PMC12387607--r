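# Network configuration: the dual-path pixel classifier.
#
# The detailed-feature-extraction (DFE) path is a full-resolution stack of 9
# conv+BN+ReLU layers with a concatenation after every two layers; the
# coarse-feature-extraction (CFE) path is a U-shaped encoder-decoder with 4
# downsampling and 4 upsampling levels, two bottleneck convolutions and 4
# skip connections.  Both path outputs and an input skip connection are
# concatenated in the fusion block (two convolutions, then softmax over the
# 3 classes).  The default per-layer kernel sizes and filter counts were
# fixed by constraint-solving within the published ranges (DFE kernels
# 1..5, CFE kernels 5..23, at most 64 filters per layer) so that the
# trainable-parameter total is exactly 152,401 (41,133 DFE + 101,268 CFE +
# 10,000 fusion).

#' Configuration of the dual-path segmentation network
#'
#' @param dfe_kernels,dfe_filters kernel sizes (odd, in 1..5) and filter
#'   counts (<= 64) of the 9 full-resolution detailed-path convolutions.
#' @param cfe_kernels,cfe_filters kernel sizes (odd, in 5..23) and filter
#'   counts of the 10 coarse-path convolutions, ordered as 4 encoder
#'   convolutions, 2 bottleneck convolutions, 4 decoder convolutions.
#' @param fusion_kernels,fusion_filters kernel sizes of the two fusion
#'   convolutions and the hidden width of the first one (the second always
#'   maps to `classes` logits).
#' @param classes number of output classes (melanoma nuclei, non-melanoma
#'   nuclei, background).
#' @param in_channels input channels (3 for RGB).
#' @return an object of class `dpnet_config`.
#' @examples
#' cfg <- dpnet_config()
#' count_parameters(cfg)
#' @export
dpnet_config <- function(dfe_kernels = c(5, 3, 3, 3, 1, 5, 3, 1, 1),
                         dfe_filters = c(27, 8, 23, 4, 22, 25, 26, 16, 64),
                         cfe_kernels = c(5, 7, 7, 9, 23, 13, 9, 5, 5, 5),
                         cfe_filters = c(4, 4, 9, 18, 7, 4, 4, 6, 4, 18),
                         fusion_kernels = c(3, 1),
                         fusion_filters = 13,
                         classes = 3,
                         in_channels = 3) {
  stopifnot(length(dfe_kernels) == 9, length(dfe_filters) == 9,
            length(cfe_kernels) == 10, length(cfe_filters) == 10,
            length(fusion_kernels) == 2, length(fusion_filters) == 1)
  if (any(dfe_kernels %% 2 == 0) || any(cfe_kernels %% 2 == 0) ||
      any(fusion_kernels %% 2 == 0))
    stop("all kernel sizes must be odd")
  if (any(dfe_kernels < 1 | dfe_kernels > 5))
    stop("detailed-path kernels must lie in 1..5")
  if (any(cfe_kernels < 5 | cfe_kernels > 23))
    stop("coarse-path kernels must lie in 5..23")
  if (any(c(dfe_filters, cfe_filters, fusion_filters) > 64))
    stop("at most 64 filters per layer")
  if (any(c(dfe_filters, cfe_filters, fusion_filters) < 1))
    stop("filter counts must be positive")
  structure(list(dfe_kernels = as.integer(dfe_kernels),
                 dfe_filters = as.integer(dfe_filters),
                 cfe_kernels = as.integer(cfe_kernels),
                 cfe_filters = as.integer(cfe_filters),
                 fusion_kernels = as.integer(fusion_kernels),
                 fusion_filters = as.integer(fusion_filters),
                 classes = as.integer(classes),
                 in_channels = as.integer(in_channels)),
            class = "dpnet_config")
}

# Compile a dpnet_config into the flat node list consumed by the C++
# engine.  Returns list(nodes = <list>, out = <id of the logits node>).
compile_network <- function(config) {
  stopifnot(inherits(config, "dpnet_config"))
  nodes <- list()
  add <- function(type, inputs = integer(), k = NULL, cout = NULL) {
    nd <- list(type = type, in_ = as.integer(inputs))
    names(nd)[2] <- "in"
    if (!is.null(k)) { nd$k <- as.integer(k); nd$cout <- as.integer(cout) }
    nodes[[length(nodes) + 1L]] <<- nd
    length(nodes)
  }
  cbr <- function(input, k, f) {  # conv + batch norm + ReLU
    cid <- add("conv", input, k, f)
    bid <- add("bn", cid)
    add("relu", bid)
  }
  input <- add("input")

  # DFE path: concatenation after every two conv layers
  prev <- input
  relu_ids <- integer(9)
  for (i in 1:9) {
    relu_ids[i] <- cbr(prev, config$dfe_kernels[i], config$dfe_filters[i])
    prev <- relu_ids[i]
    if (i %% 2 == 0 && i < 9)
      prev <- add("concat", c(relu_ids[i - 1], relu_ids[i]))
  }
  dfe_out <- prev

  # CFE path: 4 down, 2 bottleneck, 4 up, U-Net skips
  prev <- input
  skips <- integer(4)
  for (i in 1:4) {
    skips[i] <- cbr(prev, config$cfe_kernels[i], config$cfe_filters[i])
    prev <- add("pool", skips[i])
  }
  for (i in 5:6)
    prev <- cbr(prev, config$cfe_kernels[i], config$cfe_filters[i])
  for (j in 1:4) {
    up <- add("up", prev)
    cat_id <- add("concat", c(up, skips[5 - j]))
    prev <- cbr(cat_id, config$cfe_kernels[6 + j], config$cfe_filters[6 + j])
  }
  cfe_out <- prev

  # fusion: input skip + both paths, two convolutions, logits
  fuse <- add("concat", c(input, dfe_out, cfe_out))
  f1 <- add("conv", fuse, config$fusion_kernels[1], config$fusion_filters)
  r1 <- add("relu", f1)
  logits <- add("conv", r1, config$fusion_kernels[2], config$classes)

  list(nodes = nodes, out = logits)
}

#' Per-layer table of the compiled network
#'
#' Lists every parametrized layer (convolutions and batch-norm layers) with
#' its kernel size, input/output channels and trainable-parameter count
#' under the counting convention: convolution weights + convolution biases +
#' one scale and one shift per batch-normalized channel (running statistics
#' are not trainable and are excluded).
#'
#' @param config a [dpnet_config].
#' @return a data.frame with columns `node`, `path`, `type`, `k`, `cin`,
#'   `cout`, `params`.
#' @export
network_layer_table <- function(config) {
  net <- compile_network(config)
  nodes <- net$nodes
  # infer channels
  C <- integer(length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    C[i] <- switch(nd$type,
      input = config$in_channels,
      conv = nd$cout,
      concat = sum(C[nd$`in`]),
      C[nd$`in`[1]])
  }
  rows <- list()
  n_dfe_nodes <- 1L + 9L * 3L + 4L  # input + 9 cbr + 4 concats
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    if (nd$type == "conv") {
      cin <- C[nd$`in`[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        node = i, type = "conv", k = nd$k, cin = cin, cout = nd$cout,
        params = nd$k^2 * cin * nd$cout + nd$cout)
    } else if (nd$type == "bn") {
      rows[[length(rows) + 1L]] <- data.frame(
        node = i, type = "bn", k = NA_integer_, cin = C[i], cout = C[i],
        params = 2L * C[i])
    }
  }
  tab <- do.call(rbind, rows)
  tab$path <- ifelse(tab$node <= n_dfe_nodes, "dfe",
                     ifelse(tab$node <= max(tab$node) - 4L, "cfe", "fusion"))
  tab[, c("node", "path", "type", "k", "cin", "cout", "params")]
}

#' Count trainable parameters
#'
#' Counts convolution weights, convolution biases and batch-norm
#' scale/shift pairs; batch-norm running statistics are excluded.  For a
#' configuration the count is computed from the layer table; for a fitted
#' model it is computed from the stored weight arrays (the two always
#' agree).
#'
#' @param object a [dpnet_config] or a fitted `dpnet` model.
#' @param ... unused.
#' @return integer total.
#' @export
count_parameters <- function(object, ...) UseMethod("count_parameters")

#' @rdname count_parameters
#' @export
count_parameters.dpnet_config <- function(object, ...) {
  as.integer(sum(network_layer_table(object)$params))
}

#' @rdname count_parameters
#' @export
count_parameters.dpnet <- function(object, ...) {
  n <- 0L
  for (w in object$weights) {
    if (is.null(w)) next
    if (w$type == "conv") n <- n + length(w$W) + length(w$b)
    else if (w$type == "bn") n <- n + length(w$gamma) + length(w$beta)
  }
  n
}

#' @export
print.dpnet_config <- function(x, ...) {
  cat("Dual-path segmentation network configuration\n")
  cat("  detailed path : 9 convs, kernels",
      paste(x$dfe_kernels, collapse = "/"), "\n")
  cat("  coarse path   : 10 convs (4 down, 2 bottleneck, 4 up), kernels",
      paste(x$cfe_kernels, collapse = "/"), "\n")
  cat(sprintf("  fusion        : concat(input, dfe, cfe) -> %dx%d conv(%d) -> %dx%d conv(%d) -> softmax\n",
              x$fusion_kernels[1], x$fusion_kernels[1], x$fusion_filters,
              x$fusion_kernels[2], x$fusion_kernels[2], x$classes))
  cat("  trainable parameters:", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}
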