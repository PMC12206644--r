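#' Confusion-matrix performance metrics
#'
#' Computes accuracy, sensitivity, specificity, positive predictive value
#' and negative predictive value, as percentages, from predicted and true
#' labels. A metric whose denominator is zero is reported as `NA`
#' ("undefined"), never coerced to 0 or 100.
#'
#' @param predicted,truth Equal-length label vectors.
#' @param positive_label The label counted as the positive class.
#' @return An object of class `confusion_metrics`: list with counts
#'   `tp`, `fp`, `tn`, `fn` and metrics `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv` (percent, or `NA` if undefined).
#' @export
confusion_metrics <- function(predicted, truth, positive_label) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  p <- predicted == positive_label
  t <- truth == positive_label
  tp <- sum(p & t); fp <- sum(p & !t); tn <- sum(!p & !t); fn <- sum(!p & t)
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = pct(tp + tn, tp + fp + tn + fn),
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    ppv = pct(tp, tp + fp),
    npv = pct(tn, tn + fn)
  ), class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("Confusion counts: TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", v)
  cat(sprintf("  accuracy    %s\n  sensitivity %s\n  specificity %s\n  PPV         %s\n  NPV         %s\n",
              fmt(x$accuracy), fmt(x$sensitivity), fmt(x$specificity),
              fmt(x$ppv), fmt(x$npv)))
  invisible(x)
}

#' Percent suppression from CFSE dilution readouts
#'
#' `100 * (a - b) / a` where `a` is the percent CFSE dilution of responder
#' T cells cultured alone and `b` the dilution in coculture with the test
#' sample. Negative results (proliferation enhancement) are allowed and not
#' clamped.
#'
#' @param dilution_tresp_only Percent dilution of responders alone, in
#'   (0, 100].
#' @param dilution_coculture Percent dilution in coculture, in `[0, 100]`.
#' @return Percent suppression.
#' @export
percent_suppression <- function(dilution_tresp_only, dilution_coculture) {
  stopifnot(all(dilution_tresp_only >= 0), all(dilution_tresp_only <= 100),
            all(dilution_coculture >= 0), all(dilution_coculture <= 100))
  if (any(dilution_tresp_only == 0)) {
    stop("responder-only dilution of 0 leaves suppression undefined", call. = FALSE)
  }
  100 * (dilution_tresp_only - dilution_coculture) / dilution_tresp_only
}

#' Dilution-averaged suppression (AUC across titration ratios)
#'
#' Summarizes a suppression titration series over two-fold test:responder
#' dilutions (1:1, 1:2, ..., up to 1:128) as the trapezoidal area under the
#' suppression curve, by default on an x-axis of log2(dilution factor) so
#' that equal dilution steps weigh equally, divided by the x-range. The
#' result is on the same percent scale as the inputs and lies between their
#' min and max.
#'
#' @param suppression Percent-suppression values, one per ratio.
#' @param ratios Dilution factors, strictly increasing powers of two from 1
#'   to at most 128 (default `2^(0:7)` when `suppression` has 8 points).
#' @param log2_axis Integrate over log2(ratio) (default) or the raw ratio.
#' @return Dilution-averaged percent suppression.
#' @export
suppression_auc <- function(suppression, ratios = 2^(seq_along(suppression) - 1L),
                            log2_axis = TRUE) {
  if (length(suppression) < 2L) stop("need >= 2 titration points", call. = FALSE)
  if (length(ratios) != length(suppression)) {
    stop("ratios and suppression must have equal length", call. = FALSE)
  }
  if (any(duplicated(ratios)) || is.unsorted(ratios, strictly = TRUE)) {
    stop("ratios must be strictly increasing", call. = FALSE)
  }
  k <- log2(ratios)
  if (any(k != round(k)) || ratios[1L] != 1 || ratios[length(ratios)] > 128) {
    stop("ratios must be powers of two from 1 to <= 128", call. = FALSE)
  }
  x <- if (log2_axis) k else ratios
  widths <- diff(x)
  auc <- sum(widths * (suppression[-length(suppression)] + suppression[-1L]) / 2)
  auc / (x[length(x)] - x[1L])
}

#' Pearson product-moment correlation
#'
#' Thin validating wrapper around [stats::cor()] for score-vs-outcome
#' correlations: requires equal-length, non-constant inputs of length >= 3.
#'
#' @param x,y Numeric vectors.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need >= 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}
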