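# Label smoothing, smoothed cross-entropy, confusion counts, metrics.

test_that("label smoothing gives the canonical values and conserves mass", {
  y <- c(1, 0, 0, 0, 0, 0, 0, 0)
  ys <- smooth_labels(y, v = 0.1)
  expect_equal(ys[1], 0.9125)
  expect_equal(ys[2], 0.0125)
  expect_equal(sum(ys), 1)                   # one-hot mass is conserved
  expect_identical(smooth_labels(y, v = 0), y)
  # generalised conservation for arbitrary multi-hot vectors
  set.seed(1)
  for (i in 1:25) {
    y <- rbinom(8, 1, 0.4)
    v <- runif(1, 0, 0.9)
    expect_equal(sum(smooth_labels(y, v)), (1 - v) * sum(y) + v,
                 tolerance = 1e-12)
  }
  expect_error(smooth_labels(y, v = 1), "\\[0, 1\\)")
  expect_error(smooth_labels(c(0, 2), v = 0.1), "0 or 1")
})

test_that("smoothed cross-entropy matches its closed forms and an oracle", {
  onehot <- c(1, rep(0, 7))
  # v = 0 and a perfect prediction: zero loss
  expect_equal(smoothed_loss(onehot, c(1, rep(1e-7, 7))), 0, tolerance = 1e-6)
  # smoothed one-hot against the uniform prediction: log K
  ys <- smooth_labels(onehot, 0.1)
  expect_equal(smoothed_loss(ys, rep(1 / 8, 8)), log(8), tolerance = 1e-12)
  # term-by-term summation oracle on random inputs
  set.seed(2)
  for (i in 1:20) {
    ysr <- smooth_labels(rbinom(8, 1, 0.5), 0.1)
    p <- runif(8, 0.01, 1)
    expect_equal(smoothed_loss(ysr, p),
                 -sum(sapply(1:8, function(k) ysr[k] * log(p[k]))),
                 tolerance = 1e-12)
  }
  # clamping keeps the loss finite at zero probability
  expect_true(is.finite(smoothed_loss(ys, rep(0, 8))))
  expect_error(smoothed_loss(ys, rep(0.5, 4)), "length")
  # base is configurable and only rescales
  expect_equal(smoothed_loss(ys, rep(1 / 8, 8), base = 10),
               log(8) / log(10), tolerance = 1e-12)
})

test_that("confusion counts match brute-force recounting", {
  set.seed(3)
  y <- matrix(rbinom(160, 1, 0.4), 20, 8)
  p <- matrix(runif(160), 20, 8)
  cc <- confusion_counts(y, p, 0.5)
  for (k in 1:8) {
    tp <- fp <- tn <- fn <- 0L
    for (i in 1:20) {
      pred <- p[i, k] >= 0.5
      if (pred && y[i, k] == 1) tp <- tp + 1L
      if (pred && y[i, k] == 0) fp <- fp + 1L
      if (!pred && y[i, k] == 0) tn <- tn + 1L
      if (!pred && y[i, k] == 1) fn <- fn + 1L
    }
    expect_equal(unlist(cc[k, c("TP", "FP", "TN", "FN")]),
                 c(TP = tp, FP = fp, TN = tn, FN = fn))
  }
  expect_equal(rowSums(cc[, c("TP", "FP", "TN", "FN")]), rep(20, 8),
               ignore_attr = TRUE)
  # perfect and inverted predictors
  perf <- confusion_counts(y, y, 0.5)
  expect_true(all(perf$FP == 0) && all(perf$FN == 0))
  inv <- confusion_counts(y, 1 - y, 0.5)
  expect_true(all(inv$TP == 0) && all(inv$TN == 0))
  expect_error(confusion_counts(y * 2, p), "0/1")
  expect_error(confusion_counts(y, p[1:5, ]), "matching")
})

test_that("the four metrics follow their defining formulas", {
  counts <- data.frame(class = "x", TP = 2, FP = 1, TN = 0, FN = 1)
  m <- classification_metrics(counts, "per_class")
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$F1, 2 * 2 / (2 * 2 + 1 + 1))
  expect_equal(m$accuracy, 2 / 4)
  # perfect counts give all ones
  perf <- classification_metrics(
    data.frame(class = "x", TP = 5, FP = 0, TN = 7, FN = 0), "per_class")
  expect_equal(unlist(perf[, c("accuracy", "precision", "recall", "F1")]),
               c(accuracy = 1, precision = 1, recall = 1, F1 = 1))
  # zero denominators report 0 with a warning (one per degenerate formula)
  w <- capture_warnings(
    z <- classification_metrics(
      data.frame(class = "x", TP = 0, FP = 0, TN = 3, FN = 0), "per_class"))
  expect_true(any(grepl("zero denominator", w)))
  expect_equal(z$precision, 0)
  expect_error(classification_metrics(counts, "banana"))
})

test_that("micro averaging pools counts; F1 is the harmonic mean", {
  set.seed(4)
  counts <- data.frame(class = paste0("c", 1:8),
                       TP = rpois(8, 5), FP = rpois(8, 3),
                       TN = rpois(8, 10), FN = rpois(8, 2))
  micro <- classification_metrics(counts, "micro")
  pooled <- classification_metrics(
    data.frame(class = "all", TP = sum(counts$TP), FP = sum(counts$FP),
               TN = sum(counts$TN), FN = sum(counts$FN)), "per_class")
  expect_equal(micro[["precision"]], pooled$precision)
  expect_equal(micro[["F1"]], pooled$F1)
  per <- classification_metrics(counts, "per_class")
  ok <- per$precision > 0 & per$recall > 0
  expect_equal(per$F1[ok],
               2 * per$precision[ok] * per$recall[ok] /
                 (per$precision[ok] + per$recall[ok]),
               tolerance = 1e-12)
  macro <- classification_metrics(counts, "macro")
  expect_equal(macro[["F1"]], mean(per$F1))
})

test_that("metrics agree with an independent reference implementation", {
  suppressWarnings(suppressMessages(requireNamespace("caret")))
  set.seed(5)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
    prob <- runif(n)
    # keep both classes present so the reference is defined
    truth[1:2] <- c(0, 1)
    prob[1:2] <- c(0.9, 0.1)
    cc <- confusion_counts(matrix(truth, ncol = 1), matrix(prob, ncol = 1),
                           0.5)
    m <- suppressWarnings(classification_metrics(cc, "per_class"))
    pred_f <- factor(ifelse(prob >= 0.5, "pos", "neg"),
                     levels = c("pos", "neg"))
    truth_f <- factor(ifelse(truth == 1, "pos", "neg"),
                      levels = c("pos", "neg"))
    ref <- caret::confusionMatrix(pred_f, truth_f, positive = "pos",
                                  mode = "prec_recall")
    expect_equal(m$accuracy, unname(ref$overall["Accuracy"]),
                 tolerance = 1e-12)
    if (!is.na(ref$byClass["Precision"])) {
      expect_equal(m$precision, unname(ref$byClass["Precision"]),
                   tolerance = 1e-12)
    }
    expect_equal(m$recall, unname(ref$byClass["Recall"]), tolerance = 1e-12)
    if (!is.na(ref$byClass["F1"])) {
      expect_equal(m$F1, unname(ref$byClass["F1"]), tolerance = 1e-12)
    }
  }
})

test_that("write_metrics emits per-class rows plus summary rows", {
  dir <- withr::local_tempdir()
  set.seed(6)
  y <- matrix(rbinom(80, 1, 0.5), 10, 8)
  cc <- confusion_counts(y, matrix(runif(80), 10, 8), 0.5)
  path <- file.path(dir, "metrics.csv")
  suppressWarnings(write_metrics(cc, path))
  out <- utils::read.csv(path)
  expect_equal(nrow(out), 10L)  # 8 classes + micro + macro
  expect_true(all(c("micro", "macro") %in% out$class))
})
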