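# Low-level neural-network primitives.
#
# All spatial activations use the layout (H, W, N, C): height, width, batch,
# channel. Channel-last means a (H*W*N, C) matrix view is a zero-copy
# `dim<-`, so every convolution reduces to k*k GEMM calls (one per kernel
# offset) with no aperm. Gradients are exact; test coverage includes
# finite-difference checks.

# ---- padding ---------------------------------------------------------------

nn_pad <- function(x, p, value = 0) {
  if (p <= 0L) return(x)
  d <- dim(x)
  out <- array(value, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

nn_unpad <- function(x, p) {
  if (p <= 0L) return(x)
  d <- dim(x)
  x[p + seq_len(d[1] - 2L * p), p + seq_len(d[2] - 2L * p), , , drop = FALSE]
}

# Edge-replicate padding (and its adjoint for backprop): border gradients
# fold back onto the edge pixels they were copied from.
pad_rep <- function(x, p) {
  if (p <= 0L) return(x)
  d <- dim(x)
  ridx <- c(rep(1L, p), seq_len(d[1L]), rep(d[1L], p))
  cidx <- c(rep(1L, p), seq_len(d[2L]), rep(d[2L], p))
  x[ridx, cidx, , , drop = FALSE]
}

pad_rep_bwd <- function(dxp, p) {
  if (p <= 0L) return(dxp)
  d <- dim(dxp)
  h <- d[1L] - 2L * p
  w <- d[2L] - 2L * p
  # collapse rows first, then columns
  tmp <- dxp[p + seq_len(h), , , , drop = FALSE]
  for (i in seq_len(p)) {
    tmp[1, , , ] <- tmp[1, , , , drop = FALSE] + dxp[i, , , , drop = FALSE]
    tmp[h, , , ] <- tmp[h, , , , drop = FALSE] +
      dxp[p + h + i, , , , drop = FALSE]
  }
  dx <- tmp[, p + seq_len(w), , , drop = FALSE]
  for (j in seq_len(p)) {
    dx[, 1, , ] <- dx[, 1, , , drop = FALSE] + tmp[, j, , , drop = FALSE]
    dx[, w, , ] <- dx[, w, , , drop = FALSE] +
      tmp[, p + w + j, , , drop = FALSE]
  }
  dx
}

# ---- convolution -----------------------------------------------------------

# x: (H, W, N, Cin); W: (k, k, Cin, Cout); b: length-Cout or NULL.
# Cross-correlation convention (the learned-filter convention); computed as
# im2col (compiled; zero padding folded in) plus one GEMM.
conv_fwd <- function(x, W, b = NULL, stride = 1L, pad = 0L, keep = TRUE) {
  d <- dim(x)
  k <- dim(W)[1L]
  cin <- dim(W)[3L]
  cout <- dim(W)[4L]
  stopifnot(d[4L] == cin)
  ho <- (d[1L] + 2L * pad - k) %/% stride + 1L
  wo <- (d[2L] + 2L * pad - k) %/% stride + 1L
  n <- d[3L]
  m <- ho * wo * n
  cols <- cpp_im2col(x, d[1L], d[2L], n, cin, k, stride, pad)
  out <- cols %*% matrix(W, k * k * cin, cout)
  if (!is.null(b)) out <- out + rep(b, each = m)
  dim(out) <- c(ho, wo, n, cout)
  cache <- if (keep) {
    list(cols = cols, dimx = d, W = W, stride = stride,
         pad = pad, hasb = !is.null(b), ho = ho, wo = wo)
  }
  list(y = out, cache = cache)
}

conv_bwd <- function(dy, cache) {
  W <- cache$W
  d <- cache$dimx
  k <- dim(W)[1L]; cin <- dim(W)[3L]; cout <- dim(W)[4L]
  m <- cache$ho * cache$wo * d[3L]
  dym <- dy
  dim(dym) <- c(m, cout)
  dW <- crossprod(cache$cols, dym)
  dim(dW) <- dim(W)
  dcols <- tcrossprod(dym, matrix(W, k * k * cin, cout))
  dx <- cpp_col2im(dcols, d[1L], d[2L], d[3L], cin, k, cache$stride,
                   cache$pad)
  dim(dx) <- d
  db <- if (cache$hasb) colSums(dym)
  list(dx = dx, dW = dW, db = db)
}

# ---- batch normalisation ---------------------------------------------------

# Mutable numeric options for the layer stack. bn_momentum is overridden
# during post-training batch-norm recalibration (an arithmetic-mean sweep
# over the training set).
.nn_opts <- new.env(parent = emptyenv())

# Per-channel batch norm over (H, W, N). `rmean`/`rvar` are running
# statistics used at inference; training returns the updated pair. The
# column-wise passes run in compiled code (see src/bn.cpp).
bn_fwd <- function(x, gamma, beta, rmean, rvar, training,
                   momentum = .nn_opts$bn_momentum %||% 0.9, eps = 1e-5,
                   keep = TRUE) {
  d <- dim(x)
  cC <- d[4L]
  m <- prod(d[1:3])
  if (training) {
    st <- cpp_bn_stats(x, m, cC)
    mu <- st$mu
    v <- st$v
    rmean <- momentum * rmean + (1 - momentum) * mu
    rvar <- momentum * rvar + (1 - momentum) * v
  } else {
    mu <- rmean
    v <- rvar
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- cpp_scale_cols(x, m, cC, inv, -mu * inv)
  y <- cpp_scale_cols(xhat, m, cC, gamma, beta)
  dim(y) <- d
  cache <- if (keep) list(xhat = xhat, inv = inv, gamma = gamma, d = d)
  list(y = y, cache = cache, rmean = rmean, rvar = rvar)
}

bn_bwd <- function(dy, cache) {
  d <- cache$d
  m <- prod(d[1:3])
  cC <- d[4L]
  out <- cpp_bn_bwd(dy, cache$xhat, cache$gamma, cache$inv, m, cC)
  dx <- out$dx
  dim(dx) <- d
  list(dx = dx, dgamma = out$dgamma, dbeta = out$dbeta)
}

# ---- activations -----------------------------------------------------------

relu_fwd <- function(x, keep = TRUE) {
  mask <- x > 0
  y <- x * mask
  list(y = y, cache = if (keep) mask)
}

relu_bwd <- function(dy, mask) dy * mask

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- dense -----------------------------------------------------------------

dense_fwd <- function(x, W, b = NULL, keep = TRUE) {
  y <- x %*% W
  if (!is.null(b)) y <- y + rep(b, each = nrow(x))
  list(y = y, cache = if (keep) list(x = x, W = W, hasb = !is.null(b)))
}

dense_bwd <- function(dy, cache) {
  list(dx = tcrossprod(dy, cache$W),
       dW = crossprod(cache$x, dy),
       db = if (cache$hasb) colSums(dy))
}

# ---- global average pooling ------------------------------------------------

gap_fwd <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1L] * d[2L], d[3L] * d[4L])
  y <- matrix(colMeans(m), d[3L], d[4L])
  list(y = y, d = d)
}

gap_bwd <- function(dy, d) {
  hw <- d[1L] * d[2L]
  dx <- rep(as.vector(dy) / hw, each = hw)
  dim(dx) <- d
  dx
}

# ---- spatial max pooling ---------------------------------------------------

# k x k window; padding uses -Inf so border windows reduce over valid pixels.
maxpool_fwd <- function(x, k = 3L, stride = 1L, pad = 1L, keep = TRUE) {
  d <- dim(x)
  xp <- nn_pad(x, pad, value = -Inf)
  ho <- (d[1L] + 2L * pad - k) %/% stride + 1L
  wo <- (d[2L] + 2L * pad - k) %/% stride + 1L
  best <- array(-Inf, c(ho, wo, d[3L], d[4L]))
  arg <- array(0L, dim(best))
  idx <- 0L
  for (ki in seq_len(k)) {
    rows <- (seq_len(ho) - 1L) * stride + ki
    for (kj in seq_len(k)) {
      idx <- idx + 1L
      cols <- (seq_len(wo) - 1L) * stride + kj
      patch <- xp[rows, cols, , , drop = FALSE]
      sel <- patch > best
      best[sel] <- patch[sel]
      arg[sel] <- idx
    }
  }
  cache <- if (keep) {
    list(arg = arg, dimx = d, k = k, stride = stride, pad = pad,
         ho = ho, wo = wo)
  }
  list(y = best, cache = cache)
}

maxpool_bwd <- function(dy, cache) {
  d <- cache$dimx
  k <- cache$k; stride <- cache$stride; pad <- cache$pad
  ho <- cache$ho; wo <- cache$wo
  dxp <- array(0, c(d[1L] + 2L * pad, d[2L] + 2L * pad, d[3L], d[4L]))
  idx <- 0L
  for (ki in seq_len(k)) {
    rows <- (seq_len(ho) - 1L) * stride + ki
    for (kj in seq_len(k)) {
      idx <- idx + 1L
      cols <- (seq_len(wo) - 1L) * stride + kj
      dxp[rows, cols, , ] <- dxp[rows, cols, , , drop = FALSE] +
        dy * (cache$arg == idx)
    }
  }
  nn_unpad(dxp, pad)
}

# ---- dropout ---------------------------------------------------------------

# Inverted dropout; identity at inference. Draws from the session RNG.
dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) {
    return(list(y = x, mask = NULL))
  }
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(y = x * mask, mask = mask)
}

# ---- parameter-tree utilities ----------------------------------------------

# Parameters live in nested named lists; leaves are numeric arrays. Batch-norm
# running statistics are leaves named rmean/rvar and are excluded from
# optimisation.

param_flatten <- function(tree, prefix = "") {
  out <- list()
  for (nm in names(tree)) {
    leaf <- tree[[nm]]
    path <- if (nzchar(prefix)) paste0(prefix, "/", nm) else nm
    if (is.list(leaf)) {
      out <- c(out, param_flatten(leaf, path))
    } else if (!is.null(leaf)) {
      out[[path]] <- leaf
    }
  }
  out
}

param_set <- function(tree, path, value) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1L]]
  expr <- tree
  # recursive functional update
  set_rec <- function(node, parts) {
    if (length(parts) == 1L) {
      node[[parts]] <- value
      return(node)
    }
    node[[parts[1L]]] <- set_rec(node[[parts[1L]]], parts[-1L])
    node
  }
  set_rec(tree, parts)
}

param_count <- function(tree) {
  fl <- param_flatten(tree)
  fl <- fl[!grepl("(rmean|rvar)$", names(fl))]
  sum(vapply(fl, length, integer(1L)))
}

# Map every trainable leaf to zero arrays of the same shape.
param_zeros_like <- function(tree) {
  rapply(tree, function(a) array(0, dim(a) %||% length(a)), how = "replace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  fl <- param_flatten(params)
  fl <- fl[!grepl("(rmean|rvar)$", names(fl))]
  list(m = lapply(fl, function(a) a * 0),
       v = lapply(fl, function(a) a * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  gfl <- param_flatten(grads)
  pfl <- param_flatten(params)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(state$m)) {
    g <- gfl[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params <- param_set(params, nm, pfl[[nm]] - upd)
    pfl[[nm]] <- pfl[[nm]] - upd
  }
  list(params = params, state = state)
}
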