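# Training engine, evaluation, prediction, checkpointing, CLI.

small_fit <- function(ds, epochs = 2L, seed = 4L, ...) {
  cfg <- train_config(image_size = 32L, epochs = epochs, batch_size = 4L,
                      learning_rate = 1e-3, seed = seed, val_fraction = 0,
                      ...)
  bfpc_net(ds$records, config = cfg, backbone = backbone_config("tiny"),
           verbose = FALSE)
}

test_that("zero epochs returns the initial weights and an empty history", {
  ds <- make_dataset(n = 4L, size = 32L, seed = 13L)
  fit <- small_fit(ds, epochs = 0L)
  expect_equal(nrow(fit$history), 0L)
  expect_identical(fit$model$params, fit$initial_params)
})

test_that("training is bit-reproducible under a fixed seed", {
  ds <- make_dataset(n = 6L, size = 32L, seed = 14L)
  f1 <- small_fit(ds, epochs = 2L, seed = 7L)
  f2 <- small_fit(ds, epochs = 2L, seed = 7L)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(f1$model$params, f2$model$params)
  f3 <- small_fit(ds, epochs = 2L, seed = 8L)
  expect_false(identical(f1$history$train_loss, f3$history$train_loss))
})

test_that("an empty manifest fails before any epoch", {
  ds <- make_dataset(n = 4L, size = 32L, seed = 15L)
  expect_error(bfpc_net(ds$records[0, ], image_dir = ds$dir), "empty")
})

test_that("loss/head pairings are validated", {
  ds <- make_dataset(n = 4L, size = 32L, seed = 15L)
  expect_error(
    bfpc_net(ds$records,
             config = train_config(image_size = 32L, epochs = 1L,
                                   loss = "smoothed_categorical"),
             backbone = backbone_config("tiny"), verbose = FALSE),
    "softmax")
})

test_that("prediction is deterministic, ordered and checkpointable", {
  ds <- make_dataset(n = 4L, size = 32L, seed = 16L)
  fit <- small_fit(ds, epochs = 1L)
  p1 <- predict(fit, newdata = ds$records)
  p2 <- predict(fit, newdata = ds$records)
  expect_identical(p1, p2)
  expect_equal(colnames(p1), c("N", "D", "G", "C", "A", "H", "M", "O"))
  expect_equal(dim(p1), c(4L, 8L))
  # single-pair interface agrees with the batch interface
  lp <- file.path(ds$dir, ds$records$left_image[1])
  rp <- file.path(ds$dir, ds$records$right_image[1])
  p3 <- predict(fit, left = lp, right = rp)
  expect_equal(unname(p3[1, ]), unname(p1[1, ]), tolerance = 1e-12)
  # checkpoint round trip preserves behaviour
  ckpt <- file.path(ds$dir, "fit.rds")
  save_checkpoint(fit, ckpt)
  fit2 <- load_checkpoint(ckpt)
  expect_equal(predict(fit2, newdata = ds$records), p1)
  expect_error(predict(fit, left = lp), "right")
  expect_error(predict(fit, left = "nope.png", right = rp), "nope.png")
})

test_that("evaluation conserves counts and extreme thresholds behave", {
  ds <- make_dataset(n = 4L, size = 32L, seed = 17L,
                     probs = c(0, rep(0.4, 7)))
  fit <- small_fit(ds, epochs = 1L)
  ev1 <- suppressWarnings(evaluate_model(fit, ds$records[1, , drop = FALSE]))
  expect_true(all(rowSums(ev1$counts[, c("TP", "FP", "TN", "FN")]) == 1))
  # threshold 1 + probabilities < 1 means no positive predictions
  ev <- suppressWarnings(evaluate_model(fit, ds$records, threshold = 1 + 1e-9))
  expect_true(all(ev$counts$TP == 0) && all(ev$counts$FP == 0))
  pos <- ev$counts$FN > 0
  expect_true(all(ev$per_class$recall[pos] == 0))
})

test_that("engine metrics equal an independent recomputation", {
  ds <- make_dataset(n = 6L, size = 32L, seed = 18L,
                     probs = c(0, rep(0.3, 7)))
  fit <- small_fit(ds, epochs = 1L)
  ev <- suppressWarnings(evaluate_model(fit, ds$records))
  y <- as.matrix(ds$records[, c("N", "D", "G", "C", "A", "H", "M", "O")])
  recount <- confusion_counts(y, ev$prob, 0.5)
  expect_equal(ev$counts, recount)
  expect_equal(ev$micro,
               suppressWarnings(classification_metrics(recount, "micro")))
})

test_that("the CLI generates, splits and reports through the same functions", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "data")
  suppressMessages(bfpc_cli(c("generate", "--n", "10", "--size", "32",
                              "--seed", "3", "--out", out)))
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_equal(length(list.files(out, pattern = "png$")), 20L)
  sdir <- file.path(dir, "split")
  suppressMessages(bfpc_cli(c("split", "--in-manifest",
                              file.path(out, "manifest.csv"),
                              "--out-dir", sdir, "--seed", "2")))
  tr <- read_manifest(file.path(sdir, "train.csv"), image_dir = out)
  te <- read_manifest(file.path(sdir, "test.csv"), image_dir = out)
  expect_equal(nrow(tr) + nrow(te), 10L)
  expect_error(suppressMessages(bfpc_cli(c("frobnicate"))), "unknown command")
})

test_that("history CSV and checkpoint are written when a run dir is set", {
  ds <- make_dataset(n = 4L, size = 32L, seed = 19L)
  run_dir <- file.path(ds$dir, "run")
  cfg <- train_config(image_size = 32L, epochs = 1L, batch_size = 4L,
                      seed = 1L, val_fraction = 0.25,
                      checkpoint_dir = run_dir)
  fit <- bfpc_net(ds$records, config = cfg,
                  backbone = backbone_config("tiny"), verbose = FALSE)
  expect_true(file.exists(file.path(run_dir, "checkpoint.rds")))
  hist <- utils::read.csv(file.path(run_dir, "history.csv"))
  expect_equal(names(hist), c("epoch", "train_loss", "train_acc",
                              "val_loss", "val_acc"))
  expect_false(any(is.na(hist$val_loss)))
})
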