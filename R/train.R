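# Training engine: seeded mini-batch Adam over the binocular network.

#' Training configuration
#'
#' Defaults are the published training recipe: 256 x 256 inputs, Adam,
#' learning rate 0.001, 100 epochs, batch size 32, binary cross-entropy on
#' label-smoothed targets.
#'
#' @param image_size Input edge in pixels (default 256).
#' @param optimizer Optimiser name; `"adam"` is implemented.
#' @param learning_rate Adam step size (default 0.001).
#' @param epochs Number of passes over the training set (default 100).
#' @param batch_size Patients per mini-batch (default 32).
#' @param loss `"smoothed_binary"` (per-class binary cross-entropy on
#'   smoothed targets, used with the sigmoid head; default) or
#'   `"smoothed_categorical"` (the literal smoothed cross-entropy, used
#'   with the softmax head).
#' @param smoothing Label-smoothing rate `v` in `[0, 1)` (default 0.1).
#' @param lr_schedule `"constant"` (the published recipe's fixed step
#'   size; default) or `"cosine"` (cosine annealing from `learning_rate`
#'   to 5% of it over `epochs`, which consolidates the final epochs of
#'   short high-learning-rate runs).
#' @param seed Integer seed; fixes initialisation, shuffling and dropout.
#' @param checkpoint_dir Optional directory; when set, the best-validation
#'   checkpoint and the per-epoch history CSV are written there.
#' @param val_fraction Fraction of training patients carved out as a
#'   validation set for curve tracking and best-epoch selection
#'   (default 0.1; 0 disables validation).
#' @param stop_at_train_acc Optional early exit: stop once training
#'   accuracy reaches this value (e.g. 0.995 for capacity checks).
#' @return An object of class `train_config`.
#' @export
train_config <- function(image_size = 256L, optimizer = "adam",
                         learning_rate = 0.001, epochs = 100L,
                         batch_size = 32L,
                         loss = c("smoothed_binary", "smoothed_categorical"),
                         smoothing = 0.1,
                         lr_schedule = c("constant", "cosine"),
                         seed = 1L, checkpoint_dir = NULL,
                         val_fraction = 0.1, stop_at_train_acc = NULL) {
  loss <- match.arg(loss)
  lr_schedule <- match.arg(lr_schedule)
  if (!identical(tolower(optimizer), "adam")) {
    stop("only the adam optimizer is implemented", call. = FALSE)
  }
  if (epochs < 0L || batch_size <= 0L || learning_rate <= 0) {
    stop("epochs must be >= 0; batch_size and learning_rate positive",
         call. = FALSE)
  }
  structure(list(image_size = as.integer(image_size), optimizer = "adam",
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), loss = loss,
                 smoothing = smoothing, lr_schedule = lr_schedule,
                 seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir,
                 val_fraction = val_fraction,
                 stop_at_train_acc = stop_at_train_acc),
            class = "train_config")
}

# Load, normalise, enhance and augment all image pairs of a record set.
# Returns (H, W, N, 3) left/right arrays in [0, 255] plus the N x 8 label
# matrix. Augmentation ops recorded on a record are applied identically to
# both eyes, after enhancement (the ops commute with the symmetric blur).
load_pairs <- function(records, image_dir, size, enhance) {
  n <- nrow(records)
  xl <- array(0, c(size, size, n, 3L))
  xr <- array(0, c(size, size, n, 3L))
  y <- matrix(0L, n, 8L, dimnames = list(NULL, label_names()))
  for (i in seq_len(n)) {
    for (side in c("left", "right")) {
      img <- read_image(file.path(image_dir, records[[paste0(side, "_image")]][i]))
      img <- normalize_image(img, size)
      img <- weighted_enhance(img, enhance)
      ops <- records$aug_ops[i] %||% ""
      if (!is.na(ops) && nzchar(ops)) {
        for (code in strsplit(ops, "+", fixed = TRUE)[[1L]]) {
          img <- apply_augment(img, augment_op_from_code(code))
        }
      }
      if (side == "left") xl[, , i, ] <- img else xr[, , i, ] <- img
    }
    y[i, ] <- as.integer(records[i, label_names()])
  }
  list(xl = xl, xr = xr, y = y)
}

# Loss value and logit gradients for one batch.
batch_loss_grad <- function(out, ys, model, config) {
  prob <- out$prob
  n <- nrow(ys)
  fus <- model$fusion
  if (fus$mode == "prediction_average") {
    eps <- 1e-7
    p <- pmin(pmax(prob, eps), 1 - eps)
    if (config$loss == "smoothed_binary") {
      loss <- smoothed_binary_loss(ys, prob)
      dp <- (-(ys / p) + (1 - ys) / (1 - p)) / n
    } else {
      loss <- smoothed_loss(ys, prob)
      dp <- -(ys / p) / n
    }
    dpl <- dp * (fus$weights[1L] / fus$T)
    dpr <- dp * (fus$weights[2L] / fus$T)
    if (model$backbone_config$head_activation == "sigmoid") {
      dzl <- dpl * out$cache$pl * (1 - out$cache$pl)
      dzr <- dpr * out$cache$pr * (1 - out$cache$pr)
    } else {
      pl <- out$cache$pl; pr <- out$cache$pr
      dzl <- pl * (dpl - rowSums(dpl * pl))
      dzr <- pr * (dpr - rowSums(dpr * pr))
    }
    return(list(loss = loss, dz = list(dzl = dzl, dzr = dzr)))
  }
  if (config$loss == "smoothed_binary") {
    if (model$backbone_config$head_activation != "sigmoid") {
      stop("smoothed_binary loss requires the sigmoid head", call. = FALSE)
    }
    list(loss = smoothed_binary_loss(ys, prob), dz = (prob - ys) / n)
  } else {
    if (model$backbone_config$head_activation != "softmax") {
      stop("smoothed_categorical loss requires the softmax head",
           call. = FALSE)
    }
    list(loss = smoothed_loss(ys, prob),
         dz = (rowSums(ys) * prob - ys) / n)
  }
}

#' Fit the binocular fundus classifier
#'
#' Trains the two-branch attention network on a set of patient records with
#' seeded mini-batch Adam. Records are loaded once, normalised to
#' `config$image_size`, enhanced with the weighted Gaussian
#' background-subtraction, and scaled to `[0, 1]` before entering the
#' network. A validation fraction is carved out of the training records for
#' per-epoch curve tracking and best-epoch checkpoint selection; when it is
#' zero the final-epoch weights are kept. Fully reproducible for a fixed
#' seed on a single thread.
#'
#' @param records Record data frame (see [read_manifest()]).
#' @param image_dir Directory holding the images; defaults to the record
#'   set's `image_dir` attribute.
#' @param config A [train_config()].
#' @param backbone A [backbone_config()].
#' @param fusion A [fusion_config()].
#' @param enhance An [enhance_params()].
#' @param attention An [attention_params()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `bfpc_net` with elements `model` (the fitted
#'   `bfpc_model`), `history` (per-epoch data frame: epoch, train_loss,
#'   train_acc, val_loss, val_acc), `config`, `enhance`, `threshold` and
#'   `initial_params`.
#' @seealso [predict.bfpc_net()], [evaluate_model()], [save_checkpoint()]
#' @export
bfpc_net <- function(records, image_dir = NULL, config = train_config(),
                     backbone = backbone_config(), fusion = fusion_config(),
                     enhance = enhance_params(),
                     attention = attention_params(), verbose = TRUE) {
  if (nrow(records) == 0L) {
    stop("empty training manifest: nothing to train on", call. = FALSE)
  }
  image_dir <- image_dir %||% attr(records, "image_dir")
  if (is.null(image_dir)) stop("image_dir is required", call. = FALSE)
  if (backbone$head_activation == "sigmoid" &&
      config$loss == "smoothed_categorical") {
    stop("smoothed_categorical loss requires head_activation = 'softmax'",
         call. = FALSE)
  }
  if (backbone$head_activation == "softmax" &&
      config$loss == "smoothed_binary" &&
      fusion$mode != "prediction_average") {
    stop("smoothed_binary loss requires head_activation = 'sigmoid'",
         call. = FALSE)
  }

  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))

  bb <- build_backbone(backbone, attention, seed = config$seed)
  model <- new_bfpc_model(bb, fusion, n_classes = 8L, seed = config$seed)
  initial_params <- model$params

  set.seed(config$seed + 1L)
  n <- nrow(records)
  n_val <- floor(config$val_fraction * n)
  val_idx <- if (n_val > 0L) sample(n, n_val) else integer()
  train_rec <- if (n_val > 0L) records[-val_idx, , drop = FALSE] else records
  val_rec <- records[val_idx, , drop = FALSE]
  if (nrow(train_rec) == 0L) {
    stop("validation fraction leaves no training records", call. = FALSE)
  }

  tr <- load_pairs(train_rec, image_dir, config$image_size, enhance)
  va <- if (nrow(val_rec) > 0L) {
    load_pairs(val_rec, image_dir, config$image_size, enhance)
  }
  ys_tr <- smooth_labels(tr$y, config$smoothing)

  opt <- adam_init(model$params)
  nt <- nrow(train_rec)
  hist_rows <- list()
  best <- list(val_loss = Inf, params = model$params)

  set.seed(config$seed + 2L)
  for (epoch in seq_len(config$epochs)) {
    lr_epoch <- if (identical(config$lr_schedule, "cosine")) {
      config$learning_rate *
        (0.05 + 0.95 * 0.5 * (1 + cos(pi * (epoch - 1) / config$epochs)))
    } else {
      config$learning_rate
    }
    ord <- sample(nt)
    ep_loss <- 0
    correct <- 0
    total <- 0
    for (start in seq(1L, nt, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, nt)]
      xl <- tr$xl[, , idx, , drop = FALSE]
      xr <- tr$xr[, , idx, , drop = FALSE]
      out <- model_fwd(model, xl, xr, training = TRUE, keep = TRUE)
      model <- out$model   # running BN statistics advanced
      lg <- batch_loss_grad(out, ys_tr[idx, , drop = FALSE], model, config)
      grads <- model_bwd(model, lg$dz, out$cache)$g
      step <- adam_step(model$params, grads, opt, lr = lr_epoch)
      model$params <- step$params
      opt <- step$state
      ep_loss <- ep_loss + lg$loss * length(idx)
      pred <- out$prob >= 0.5
      correct <- correct + sum(pred == (tr$y[idx, , drop = FALSE] == 1L))
      total <- total + length(pred)
    }
    train_loss <- ep_loss / nt
    train_acc <- correct / total
    val_loss <- NA_real_
    val_acc <- NA_real_
    if (!is.null(va)) {
      ev <- eval_pass(model, va, config)
      val_loss <- ev$loss
      val_acc <- ev$acc
      if (val_loss < best$val_loss) {
        best <- list(val_loss = val_loss, params = model$params)
      }
    }
    hist_rows[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                     train_acc = train_acc,
                                     val_loss = val_loss, val_acc = val_acc)
    if (verbose) {
      message(sprintf(
        "epoch %3d  loss %.4f  acc %.4f  val_loss %s  val_acc %s",
        epoch, train_loss, train_acc,
        ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss)),
        ifelse(is.na(val_acc), "-", sprintf("%.4f", val_acc))))
    }
    if (!is.null(config$stop_at_train_acc) &&
        train_acc >= config$stop_at_train_acc) break
  }
  history <- if (length(hist_rows) > 0L) {
    do.call(rbind, hist_rows)
  } else {
    data.frame(epoch = integer(), train_loss = numeric(),
               train_acc = numeric(), val_loss = numeric(),
               val_acc = numeric())
  }
  if (!is.null(va) && is.finite(best$val_loss)) {
    model$params <- best$params
  }
  # Recalibrate batch-norm running statistics with one arithmetic-mean
  # sweep over the training set at the final weights. The rectified
  # attention gains are unbounded, so activation statistics drift during
  # training and the exponential running averages can lag; this removes the
  # train/eval normalisation gap.
  if (config$epochs > 0L) {
    bi <- 0L
    for (start in seq(1L, nt, by = config$batch_size)) {
      idx <- start:min(start + config$batch_size - 1L, nt)
      bi <- bi + 1L
      .nn_opts$bn_momentum <- (bi - 1) / bi
      out <- model_fwd(model, tr$xl[, , idx, , drop = FALSE],
                       tr$xr[, , idx, , drop = FALSE],
                       training = TRUE, keep = FALSE)
      model <- out$model
    }
    rm("bn_momentum", envir = .nn_opts)
  }
  fit <- structure(list(model = model, history = history, config = config,
                        enhance = enhance, fusion = model$fusion,
                        backbone_config = model$backbone_config,
                        attention = model$attention,
                        threshold = 0.5,
                        initial_params = initial_params,
                        n_train = nt, n_val = nrow(val_rec)),
                   class = "bfpc_net")
  if (!is.null(config$checkpoint_dir)) {
    dir.create(config$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
    save_checkpoint(fit, file.path(config$checkpoint_dir, "checkpoint.rds"))
    utils::write.csv(history,
                     file.path(config$checkpoint_dir, "history.csv"),
                     row.names = FALSE)
  }
  fit
}

# Loss/accuracy on a loaded pair set without updating anything.
eval_pass <- function(model, data, config) {
  out <- model_fwd(model, data$xl, data$xr, training = FALSE, keep = FALSE)
  ys <- smooth_labels(data$y, config$smoothing)
  loss <- if (config$loss == "smoothed_binary" &&
              model$fusion$mode != "prediction_average") {
    smoothed_binary_loss(ys, out$prob)
  } else if (config$loss == "smoothed_binary") {
    smoothed_binary_loss(ys, out$prob)
  } else {
    smoothed_loss(ys, out$prob)
  }
  acc <- mean((out$prob >= 0.5) == (data$y == 1L))
  list(loss = loss, acc = acc, prob = out$prob)
}

#' Evaluate a fitted model on a record set
#'
#' Runs the forward pass on every patient pair, thresholds the per-class
#' probabilities, and reports per-class confusion counts with accuracy,
#' precision, recall and F1, plus micro and macro averages.
#'
#' @param fit A fitted [bfpc_net()] object (or a loaded checkpoint).
#' @param records Record data frame.
#' @param image_dir Image directory; defaults to the record attribute.
#' @param threshold Decision threshold in (0, 1]; default the fit's 0.5.
#' @return An object of class `bfpc_eval`: list with `counts`, `per_class`,
#'   `micro`, `macro`, `n`, `prob`, `labels`.
#' @export
evaluate_model <- function(fit, records, image_dir = NULL, threshold = NULL) {
  stopifnot(inherits(fit, "bfpc_net"))
  image_dir <- image_dir %||% attr(records, "image_dir")
  threshold <- threshold %||% fit$threshold
  if (!all(label_names() %in% names(records))) {
    stop("records lack the 8 class columns expected by the checkpoint",
         call. = FALSE)
  }
  data <- load_pairs(records, image_dir, fit$config$image_size, fit$enhance)
  out <- model_fwd(fit$model, data$xl, data$xr, training = FALSE,
                   keep = FALSE)
  counts <- confusion_counts(data$y, out$prob, threshold)
  structure(list(counts = counts,
                 per_class = classification_metrics(counts, "per_class"),
                 micro = classification_metrics(counts, "micro"),
                 macro = classification_metrics(counts, "macro"),
                 n = nrow(records), prob = out$prob, labels = data$y,
                 threshold = threshold),
            class = "bfpc_eval")
}

#' Save / load a self-describing checkpoint
#'
#' The checkpoint holds the full fitted object: weights plus backbone,
#' fusion, enhancement and training configurations, so prediction needs no
#' external state.
#'
#' @param fit A fitted `bfpc_net` object.
#' @param path Destination file.
#' @return `save_checkpoint`: the path, invisibly. `load_checkpoint`: the
#'   restored `bfpc_net` object.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "bfpc_net"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "bfpc_net")) {
    stop("file does not contain a bfpc_net checkpoint", call. = FALSE)
  }
  fit
}
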