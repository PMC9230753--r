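# Functional single-map interface to the attention operators.
#
# Feature maps at this interface follow the C x H x W convention (channel
# first, as feature-map shapes are usually quoted); internally the package
# computes in (H, W, batch, C).

chw_to_internal <- function(fmap) {
  d <- dim(fmap)
  if (length(d) != 3L) stop("feature map must be a C x H x W array", call. = FALSE)
  x <- aperm(fmap, c(2L, 3L, 1L))
  dim(x) <- c(d[2L], d[3L], 1L, d[1L])
  x
}

internal_to_chw <- function(x) {
  d <- dim(x)
  y <- x
  dim(y) <- c(d[1L], d[2L], d[4L])
  aperm(y, c(3L, 1L, 2L))
}

#' Weights for a channel-attention map
#'
#' Two independently parameterised bottleneck dense maps (`C -> C/r -> C`)
#' sharing one pooled descriptor. Use this to obtain a correctly shaped,
#' seeded random weight set, then overwrite entries for controlled
#' experiments.
#'
#' @param channels Channel count `C`.
#' @param params An [attention_params()]; `channel_reduction` must divide
#'   `channels`.
#' @param seed Integer seed.
#' @return Named list `W1a, b1a, W2a, b2a, W1b, b1b, W2b, b2b`.
#' @export
channel_attention_weights <- function(channels, params = attention_params(),
                                      seed = 1L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  init_ca(as.integer(channels), params$channel_reduction)
}

#' Weights for a spatial-attention map
#'
#' @param params An [attention_params()]; `spatial_kernel` sets the size of
#'   the single 1-to-1-channel convolution.
#' @param seed Integer seed.
#' @return Named list `W` (k x k x 1 x 1 kernel) and scalar bias `b`.
#' @export
spatial_attention_weights <- function(params = attention_params(),
                                      seed = 1L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  init_sa(params$spatial_kernel)
}

#' Channel attention
#'
#' Global average pooling over H x W gives a C-vector descriptor; two
#' independent bottleneck dense maps are applied to it, summed, rectified
#' (ReLU), and the resulting vector rescales the input channel-wise. The
#' output shape equals the input shape.
#'
#' @param fmap `C x H x W` feature array (role F', the output of the
#'   block's pre-convolutions).
#' @param weights Weight list as from [channel_attention_weights()].
#' @param params An [attention_params()] (consistency checks only).
#' @return `C x H x W` array, role U.
#' @export
channel_attention <- function(fmap, weights = NULL,
                              params = attention_params()) {
  x <- chw_to_internal(fmap)
  C <- dim(x)[4L]
  if (C %% params$channel_reduction != 0L) {
    stop(sprintf("channel count %d not divisible by channel_reduction %d",
                 C, params$channel_reduction), call. = FALSE)
  }
  if (is.null(weights)) weights <- channel_attention_weights(C, params)
  internal_to_chw(ca_fwd(x, weights, keep = FALSE)$y)
}

#' Spatial attention
#'
#' The channel-wise mean collapses the input to a 1 x H x W map; a stride-1
#' 3x3 spatial max pool is applied on top; a single odd-kernel 1-to-1
#' convolution (dimension-preserving padding) maps the pooled map to an
#' attention map, which is multiplied elementwise with the pooled map and
#' broadcast across all C channels. The output shape equals the input shape,
#' as required for the residual merge.
#'
#' @param fmap `C x H x W` feature array (role U).
#' @param weights Weight list as from [spatial_attention_weights()].
#' @param params An [attention_params()].
#' @return `C x H x W` array, role U'.
#' @export
spatial_attention <- function(fmap, weights = NULL,
                              params = attention_params()) {
  if (params$spatial_kernel %% 2L == 0L) {
    stop("spatial_kernel must be odd", call. = FALSE)
  }
  x <- chw_to_internal(fmap)
  if (is.null(weights)) weights <- spatial_attention_weights(params)
  internal_to_chw(sa_fwd(x, weights, keep = FALSE)$y)
}

#' Weights for a full residual attention block
#'
#' @param channels Channel count of the block input.
#' @param params An [attention_params()].
#' @param seed Integer seed.
#' @return Named list with `pre` (conv+BN pre-layers), `ca`, `sa`.
#' @export
residual_attention_weights <- function(channels, params = attention_params(),
                                       seed = 1L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  init_ram(as.integer(channels), params)
}

#' Residual attention block
#'
#' The composition: pre-convolutions give F', channel attention gives U,
#' spatial attention gives U', and the block output is the rectified
#' residual merge `M = ReLU(U' + F)` with F the block input. All roles
#' share the `C x H x W` shape.
#'
#' @param fmap `C x H x W` feature array (role F).
#' @param weights Weight list as from [residual_attention_weights()]. A
#'   `pre` entry of length zero skips the pre-convolutions (F' = F).
#' @param params An [attention_params()].
#' @return `C x H x W` array, role M.
#' @export
residual_attention_block <- function(fmap, weights = NULL,
                                     params = attention_params()) {
  x <- chw_to_internal(fmap)
  C <- dim(x)[4L]
  if (is.null(weights)) weights <- residual_attention_weights(C, params)
  internal_to_chw(ram_fwd(x, weights, training = FALSE, keep = FALSE)$y)
}
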