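# Full binocular network: shared branch, fusion, head.

# Build the complete model parameter tree (branch + head).
new_bfpc_model <- function(backbone, fusion, n_classes = 8L, seed = 1L) {
  stopifnot(inherits(backbone, "bfpc_backbone"),
            inherits(fusion, "fusion_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed) + 7L)
  ed <- backbone$config$embedding_dim
  hin <- if (fusion$mode == "feature_concat") 2L * ed else ed
  params <- list(branch = backbone$params,
                 head = init_dense(hin, n_classes))
  structure(list(params = params,
                 backbone_config = backbone$config,
                 attention = backbone$attention,
                 plan = backbone$plan,
                 fusion = fusion,
                 n_classes = as.integer(n_classes)),
            class = "bfpc_model")
}

# Forward pass of the full network on a batch of patients.
# xl, xr: (H, W, N, 3) arrays of preprocessed images in [0, 255].
# Returns per-class probabilities (N x K), plus caches when keep = TRUE.
model_fwd <- function(model, xl, xr, training = FALSE, keep = training) {
  n <- dim(xl)[3L]
  x <- array(0, c(dim(xl)[1L], dim(xl)[2L], 2L * n, 3L))
  x[, , seq_len(n), ] <- xl / 255
  x[, , n + seq_len(n), ] <- xr / 255
  br <- branch_fwd(x, model$params$branch, model$plan,
                   model$backbone_config, training, keep)
  model$params$branch <- br$params
  el <- br$emb[seq_len(n), , drop = FALSE]
  er <- br$emb[n + seq_len(n), , drop = FALSE]
  fus <- model$fusion
  cfg <- model$backbone_config
  act <- function(z) {
    if (cfg$head_activation == "sigmoid") sigmoid(z) else softmax_rows(z)
  }
  if (fus$mode == "prediction_average") {
    hl <- head_one_fwd(el, model$params$head, cfg, training, keep)
    hr <- head_one_fwd(er, model$params$head, cfg, training, keep)
    pl <- act(hl$z)
    pr <- act(hr$z)
    prob <- (fus$weights[1L] * pl + fus$weights[2L] * pr) / fus$T
    cache <- if (keep) list(branch = br$cache, hl = hl$cache, hr = hr$cache,
                            pl = pl, pr = pr, n = n)
    return(list(prob = prob, model = model, cache = cache,
                logits = NULL))
  }
  zin <- if (fus$mode == "feature_average") {
    (fus$weights[1L] * el + fus$weights[2L] * er) / fus$T
  } else {
    cbind(el, er)
  }
  hd <- head_one_fwd(zin, model$params$head, cfg, training, keep)
  prob <- act(hd$z)
  cache <- if (keep) list(branch = br$cache, hd = hd$cache, n = n)
  list(prob = prob, model = model, cache = cache, logits = hd$z)
}

# Shared head: ReLU -> dropout -> dense to K logits.
head_one_fwd <- function(emb, p, cfg, training, keep) {
  rl <- relu_fwd(emb, keep)
  dr <- dropout_fwd(rl$y, cfg$dropout_rate, training)
  de <- dense_fwd(dr$y, p$W, p$b, keep)
  list(z = de$y,
       cache = if (keep) list(rl = rl$cache, dr = dr$mask, de = de$cache))
}

head_one_bwd <- function(dz, cache) {
  de <- dense_bwd(dz, cache$de)
  dx <- de$dx
  if (!is.null(cache$dr)) dx <- dx * cache$dr
  dx <- relu_bwd(dx, cache$rl)
  list(dx = dx, g = list(W = de$dW, b = de$db))
}

# Backward pass. For the feature modes `dz` is the gradient w.r.t. head
# logits; for prediction_average it is the gradient w.r.t. the two
# per-branch logit matrices (list(dzl, dzr)).
model_bwd <- function(model, dz, cache) {
  fus <- model$fusion
  n <- cache$n
  ghead <- NULL
  if (fus$mode == "prediction_average") {
    hl <- head_one_bwd(dz$dzl, cache$hl)
    hr <- head_one_bwd(dz$dzr, cache$hr)
    ghead <- list(W = hl$g$W + hr$g$W, b = hl$g$b + hr$g$b)
    del <- hl$dx
    der <- hr$dx
  } else {
    hd <- head_one_bwd(dz, cache$hd)
    ghead <- hd$g
    if (fus$mode == "feature_average") {
      del <- hd$dx * (fus$weights[1L] / fus$T)
      der <- hd$dx * (fus$weights[2L] / fus$T)
    } else {
      ed <- ncol(hd$dx) %/% 2L
      del <- hd$dx[, seq_len(ed), drop = FALSE]
      der <- hd$dx[, ed + seq_len(ed), drop = FALSE]
    }
  }
  demb <- rbind(del, der)
  br <- branch_bwd(demb, cache$branch, model$params$branch)
  list(g = list(branch = br$g, head = ghead))
}

#' Forward pass on one preprocessed image pair
#'
#' Runs the two shared-weight branches, fuses them and applies the head,
#' returning the eight per-class probabilities in the order
#' N, D, G, C, A, H, M, O. With the sigmoid head every output lies in
#' `[0, 1]`; with the softmax head the outputs additionally sum to 1.
#'
#' @param model A `bfpc_model` (see [bfpc_net()]; the fitted object's
#'   `$model` element) .
#' @param left,right Preprocessed `(size, size, 3)` arrays in `[0, 255]` of
#'   the configured input size.
#' @return Named numeric vector of 8 probabilities.
#' @export
forward_pair <- function(model, left, right) {
  stopifnot(inherits(model, "bfpc_model"))
  check_rgb(left); check_rgb(right)
  if (!identical(dim(left), dim(right)) || dim(left)[1L] != dim(left)[2L]) {
    stop("left and right must be square images of identical size; ",
         "preprocess with normalize_image() first", call. = FALSE)
  }
  xl <- aperm(array(left, c(dim(left), 1L)), c(1L, 2L, 4L, 3L))
  xr <- aperm(array(right, c(dim(right), 1L)), c(1L, 2L, 4L, 3L))
  out <- model_fwd(model, xl, xr, training = FALSE, keep = FALSE)
  stats::setNames(as.numeric(out$prob[1L, ]),
                  label_names()[seq_len(model$n_classes)])
}
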