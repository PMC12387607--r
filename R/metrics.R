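# Confusion counting and the evaluation metric suite: accuracy, precision,
# recall, Dice coefficient and Jaccard score, all derived from per-pixel
# TP/TN/FP/FN counts.

#' Confusion counts
#'
#' @param tp,tn,fp,fn nonnegative pixel counts.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  structure(as.list(counts), total = sum(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("actual +", "actual -"),
                              c("pred +", "pred -")))
  print(format(m, big.mark = ","), quote = FALSE)
  cat("total:", format(attr(x, "total"), big.mark = ","), "pixels\n")
  invisible(x)
}

#' Binarize a class map for nuclei-level evaluation
#'
#' Positive = nuclei of either type (classes 1 and 2), negative =
#' background (class 3).
#'
#' @param cm `H x W` integer class map in 1..3.
#' @return binary (0/1) integer matrix.
#' @export
binarize_nuclei <- function(cm) {
  stopifnot(all(cm %in% 1:3))
  (cm <= 2L) * 1L
}

#' Binarize a class map for melanoma-level evaluation
#'
#' Positive = melanoma nuclei only (class 1).
#'
#' @inheritParams binarize_nuclei
#' @return binary (0/1) integer matrix.
#' @export
binarize_melanoma <- function(cm) {
  stopifnot(all(cm %in% 1:3))
  (cm == 1L) * 1L
}

#' Confusion counts from a pair of binary maps
#'
#' @param pred,truth binary (0/1) matrices of equal dims.
#' @return a [confusion_counts] whose four counts sum to the number of
#'   evaluated pixels.
#' @export
confusion_from_maps <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("map dims differ")
  p <- pred == 1; tr <- truth == 1
  confusion_counts(tp = sum(p & tr), tn = sum(!p & !tr),
                   fp = sum(p & !tr), fn = sum(!p & tr))
}

#' Evaluation metrics from confusion counts
#'
#' Computes accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, Dice `2 x precision x recall / (precision + recall)`
#' (equivalently `2TP/(2TP+FP+FN)`) and Jaccard `TP/(TP+FP+FN)`.  A metric
#' whose denominator is zero is reported as `NaN` with a warning rather
#' than silently coerced to 0.
#'
#' @param cc a [confusion_counts] with at least one positive count.
#' @param level evaluation label recorded in the report header, e.g.
#'   `"nuclei"` (classes 1+2 vs 3) or `"melanoma"` (class 1 vs rest).
#' @return an object of class `metrics_report`: fractions in `[0, 1]` plus
#'   the counts.  `print()` shows half-up-rounded percentages to 2
#'   decimals; [report_percentages()] returns them.
#' @export
compute_metrics <- function(cc, level = "nuclei") {
  stopifnot(inherits(cc, "confusion_counts"))
  tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("all counts are zero")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " is undefined (zero denominator); reported as NaN")
      return(NaN)
    }
    num / den
  }
  structure(list(accuracy = (tp + tn) / total,
                 precision = safe_div(tp, tp + fp, "precision"),
                 recall = safe_div(tp, tp + fn, "recall"),
                 dice = safe_div(2 * tp, 2 * tp + fp + fn, "Dice"),
                 jaccard = safe_div(tp, tp + fp + fn, "Jaccard"),
                 counts = cc, level = level),
            class = "metrics_report")
}

# half-up rounding (R's round() is half-even)
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Metric percentages at report precision
#'
#' @param mr a `metrics_report`.
#' @param digits decimals of the percentage (default 2, half-up rounding).
#' @return named numeric vector of percentages.
#' @export
report_percentages <- function(mr, digits = 2) {
  stopifnot(inherits(mr, "metrics_report"))
  v <- unlist(mr[c("accuracy", "precision", "recall", "dice", "jaccard")])
  round_half_up(100 * v, digits)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Segmentation metrics (positive class: ", x$level, ")\n", sep = "")
  p <- report_percentages(x)
  for (nm in names(p))
    cat(sprintf("  %-9s %6.2f %%\n", nm, p[nm]))
  cat("  counts: TP", format(x$counts$tp, big.mark = ","),
      " TN", format(x$counts$tn, big.mark = ","),
      " FP", format(x$counts$fp, big.mark = ","),
      " FN", format(x$counts$fn, big.mark = ","), "\n")
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(level = x$level, accuracy = x$accuracy, precision = x$precision,
             recall = x$recall, dice = x$dice, jaccard = x$jaccard,
             tp = x$counts$tp, tn = x$counts$tn, fp = x$counts$fp,
             fn = x$counts$fn)
}

#' Convert a Dice coefficient to a Jaccard score
#'
#' Uses the algebraic identity `J = D / (2 - D)` that follows from the
#' count definitions `D = 2TP/(2TP+FP+FN)` and `J = TP/(TP+FP+FN)`.
#'
#' @param d Dice coefficient(s) in `[0, 1]`.
#' @return Jaccard score(s) in `[0, 1]`.
#' @export
dice_to_jaccard <- function(d) {
  stopifnot(all(d >= 0 & d <= 1))
  d / (2 - d)
}
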