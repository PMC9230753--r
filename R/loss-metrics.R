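# Label smoothing, smoothed cross-entropy losses, confusion counts and the
# four evaluation metrics (accuracy, precision, recall, F1).

#' Smooth multi-hot labels
#'
#' Elementwise `y'_k = (1 - v) * y_k + v / K`, where `v` is the smoothing
#' (error) rate and `K` the number of classes. With the defaults `v = 0.1`,
#' `K = 8`, positive labels map to 0.9125 and negative labels to 0.0125;
#' for a one-hot vector the smoothed entries still sum to one.
#'
#' @param y Numeric vector or matrix (rows = samples) with entries in {0, 1}.
#' @param v Smoothing rate in `[0, 1)`.
#' @param K Number of classes; defaults to the label dimension of `y`.
#' @return Smoothed labels, same shape as `y`.
#' @export
smooth_labels <- function(y, v = 0.1, K = NULL) {
  if (!is.numeric(v) || length(v) != 1L || v < 0 || v >= 1) {
    stop("v must be a single value in [0, 1)", call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) {
    stop("y entries must be 0 or 1", call. = FALSE)
  }
  if (is.null(K)) K <- if (is.matrix(y)) ncol(y) else length(y)
  (1 - v) * y + v / K
}

#' Smoothed cross-entropy loss
#'
#' `-sum_k y'_k * log(p_k)` for one sample, or the mean of that quantity
#' over rows of a matrix. Natural logarithm by default (the base only
#' rescales the loss); predicted probabilities are clamped below at `clamp`
#' to keep the loss finite.
#'
#' @param y_smooth Smoothed labels (vector or matrix).
#' @param y_hat Predicted probabilities, same shape.
#' @param base Logarithm base, default `exp(1)`.
#' @param clamp Lower clamp on probabilities, default `1e-7`.
#' @return Scalar loss.
#' @export
smoothed_loss <- function(y_smooth, y_hat, base = exp(1), clamp = 1e-7) {
  if (length(y_smooth) != length(y_hat)) {
    stop("y_smooth and y_hat must have the same length", call. = FALSE)
  }
  p <- pmax(y_hat, clamp)
  tot <- -sum(y_smooth * log(p, base = base))
  n <- if (is.matrix(y_smooth)) nrow(y_smooth) else 1L
  tot / n
}

# Smoothed per-class binary cross-entropy (the multi-label companion used
# with the sigmoid head): -sum_k [y' log p + (1 - y') log(1 - p)].
smoothed_binary_loss <- function(y_smooth, y_hat, clamp = 1e-7) {
  if (length(y_smooth) != length(y_hat)) {
    stop("y_smooth and y_hat must have the same length", call. = FALSE)
  }
  p <- pmin(pmax(y_hat, clamp), 1 - clamp)
  tot <- -sum(y_smooth * log(p) + (1 - y_smooth) * log1p(-p))
  n <- if (is.matrix(y_smooth)) nrow(y_smooth) else 1L
  tot / n
}

#' Per-class confusion counts
#'
#' Thresholds probabilities at `threshold` (prediction positive when
#' `p >= threshold`) and accumulates TP/FP/TN/FN per class.
#'
#' @param y_true `N x K` multi-hot matrix of 0/1 labels.
#' @param y_prob `N x K` matrix of predicted probabilities.
#' @param threshold Decision threshold in (0, 1]; default 0.5.
#' @return Data frame with columns class, TP, FP, TN, FN; class `K` rows.
#' @export
confusion_counts <- function(y_true, y_prob, threshold = 0.5) {
  y_true <- as.matrix(y_true)
  y_prob <- as.matrix(y_prob)
  if (!all(dim(y_true) == dim(y_prob))) {
    stop("y_true and y_prob must have matching shapes", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1))) {
    stop("y_true must be a 0/1 multi-hot matrix", call. = FALSE)
  }
  pred <- y_prob >= threshold
  truth <- y_true == 1
  cls <- colnames(y_true) %||% label_names()[seq_len(ncol(y_true))]
  data.frame(
    class = cls,
    TP = colSums(pred & truth),
    FP = colSums(pred & !truth),
    TN = colSums(!pred & !truth),
    FN = colSums(!pred & truth),
    row.names = NULL, stringsAsFactors = FALSE)
}

metric_formulas <- function(TP, FP, TN, FN) {
  safe <- function(num, den) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0)) {
      warning("zero denominator in a metric; reporting 0", call. = FALSE)
    }
    out
  }
  data.frame(
    accuracy = safe(TP + TN, TP + FP + TN + FN),
    precision = safe(TP, TP + FP),
    recall = safe(TP, TP + FN),
    F1 = safe(2 * TP, 2 * TP + FP + FN))
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Applies `accuracy = (TP + TN) / (TP + FP + TN + FN)`,
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)` and
#' `F1 = 2 TP / (2 TP + FP + FN)` either per class, to pooled counts
#' (micro), or as the unweighted mean over classes (macro). Zero
#' denominators yield 0 with a warning.
#'
#' @param counts Data frame from [confusion_counts()].
#' @param averaging One of `"per_class"`, `"micro"`, `"macro"`.
#' @return For `per_class`, a data frame of counts plus the four metrics;
#'   otherwise a named numeric vector of the four metrics.
#' @export
classification_metrics <- function(counts,
                                   averaging = c("per_class", "micro",
                                                 "macro")) {
  averaging <- match.arg(averaging)
  per <- metric_formulas(counts$TP, counts$FP, counts$TN, counts$FN)
  switch(averaging,
    per_class = cbind(counts, per),
    micro = {
      m <- metric_formulas(sum(counts$TP), sum(counts$FP),
                           sum(counts$TN), sum(counts$FN))
      unlist(m[1L, ])
    },
    macro = colMeans(per))
}

#' Write a metrics report CSV
#'
#' One row per class (counts plus the four metrics) followed by micro- and
#' macro-average summary rows.
#'
#' @param counts Data frame from [confusion_counts()].
#' @param path Destination CSV path.
#' @return The path, invisibly.
#' @export
write_metrics <- function(counts, path) {
  per <- classification_metrics(counts, "per_class")
  micro <- classification_metrics(counts, "micro")
  macro <- classification_metrics(counts, "macro")
  summary_rows <- data.frame(
    class = c("micro", "macro"),
    TP = c(sum(counts$TP), NA), FP = c(sum(counts$FP), NA),
    TN = c(sum(counts$TN), NA), FN = c(sum(counts$FN), NA),
    accuracy = c(micro[["accuracy"]], macro[["accuracy"]]),
    precision = c(micro[["precision"]], macro[["precision"]]),
    recall = c(micro[["recall"]], macro[["recall"]]),
    F1 = c(micro[["F1"]], macro[["F1"]]),
    stringsAsFactors = FALSE)
  utils::write.csv(rbind(per, summary_rows), path, row.names = FALSE)
  invisible(path)
}
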