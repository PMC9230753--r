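# S3 methods for fitted models and evaluation reports.

#' @export
print.bfpc_net <- function(x, ...) {
  cfg <- x$backbone_config
  cat("Binocular fundus classifier (bfpc_net)\n")
  cat(sprintf("  backbone: %s (%d stages, attention after %s)\n",
              cfg$variant, cfg$n_stages,
              if (length(cfg$insertion_points)) {
                paste(cfg$insertion_points, collapse = ", ")
              } else "none"))
  cat(sprintf("  fusion: %s, weights (%s); head: %s\n",
              x$fusion$mode, paste(x$fusion$weights, collapse = ", "),
              cfg$head_activation))
  cat(sprintf("  input %dx%d, embedding %d, %s parameters\n",
              x$config$image_size, x$config$image_size, cfg$embedding_dim,
              format(param_count(x$model$params), big.mark = ",")))
  cat(sprintf("  trained %d epochs on %d patients (%d validation)\n",
              nrow(x$history), x$n_train, x$n_val))
  if (nrow(x$history) > 0L) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final: train loss %.4f, train accuracy %.4f\n",
                last$train_loss, last$train_acc))
  }
  invisible(x)
}

#' @export
summary.bfpc_net <- function(object, ...) {
  print(object)
  if (nrow(object$history) > 0L) {
    cat("\nTraining history (last 5 epochs):\n")
    print(utils::tail(object$history, 5L), row.names = FALSE)
  }
  invisible(object)
}

#' Plot training and validation curves
#'
#' @param x A fitted `bfpc_net`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.bfpc_net <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0L) {
    warning("no training history to plot", call. = FALSE)
    return(invisible(x))
  }
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red3"), xlab = "epoch",
                    ylab = "loss", main = "Loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red3"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l",
                    lty = 1, col = c("black", "red3"), xlab = "epoch",
                    ylab = "accuracy", main = "Accuracy", ...)
  invisible(x)
}

#' Predict per-class probabilities for patients
#'
#' Applies the checkpoint's stored preprocessing (square resize to the
#' configured input size, weighted Gaussian enhancement) to each image pair
#' and runs the network. Output columns follow the fixed label order
#' N, D, G, C, A, H, M, O.
#'
#' @param object A fitted `bfpc_net`.
#' @param newdata Either a record data frame (see [read_manifest()]) or
#'   `NULL` when `left`/`right` are given.
#' @param left,right Paths of a single raw image pair (alternative to
#'   `newdata`).
#' @param image_dir Image directory for `newdata`.
#' @param type `"prob"` (default) for probabilities, `"class"` for 0/1
#'   calls at the fit's threshold.
#' @param ... Unused.
#' @return Numeric matrix (patients x 8), rownames = patient ids when
#'   available.
#' @export
predict.bfpc_net <- function(object, newdata = NULL, left = NULL,
                             right = NULL, image_dir = NULL,
                             type = c("prob", "class"), ...) {
  type <- match.arg(type)
  size <- object$config$image_size
  prep <- function(path) {
    weighted_enhance(normalize_image(read_image(path), size), object$enhance)
  }
  if (is.null(newdata)) {
    if (is.null(left) || is.null(right)) {
      stop("provide either newdata or both left and right image paths",
           call. = FALSE)
    }
    prob <- matrix(forward_pair(object$model, prep(left), prep(right)),
                   1L, 8L, dimnames = list(NULL, label_names()))
  } else {
    image_dir <- image_dir %||% attr(newdata, "image_dir")
    n <- nrow(newdata)
    prob <- matrix(0, n, 8L,
                   dimnames = list(newdata$id, label_names()))
    for (i in seq_len(n)) {
      l <- prep(file.path(image_dir, newdata$left_image[i]))
      r <- prep(file.path(image_dir, newdata$right_image[i]))
      prob[i, ] <- forward_pair(object$model, l, r)
    }
  }
  if (type == "class") (prob >= object$threshold) * 1L else prob
}

#' @export
print.bfpc_eval <- function(x, ...) {
  cat(sprintf("Evaluation on %d patients (threshold %.2f)\n\n", x$n,
              x$threshold))
  per <- x$per_class
  per[, c("accuracy", "precision", "recall", "F1")] <-
    round(per[, c("accuracy", "precision", "recall", "F1")], 4)
  print(per, row.names = FALSE)
  cat(sprintf("\nmicro: accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$micro[["accuracy"]], x$micro[["precision"]],
              x$micro[["recall"]], x$micro[["F1"]]))
  cat(sprintf("macro: accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$macro[["accuracy"]], x$macro[["precision"]],
              x$macro[["recall"]], x$macro[["F1"]]))
  invisible(x)
}
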