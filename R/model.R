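# The binocular classifier: residual backbone with residual attention
# blocks, and the two-branch fusion head.
#
# A residual attention block maps a feature tensor F (C channels) to
# M = ReLU(U' + F):
#   F'  three (configurable) channel-preserving 3x3 conv+BN+ReLU layers;
#   U   channel attention: the globally average-pooled C-vector of F' is
#       passed through two independently parameterised bottleneck dense maps
#       (C -> C/r -> C), their sum is rectified (ReLU, not sigmoid), and the
#       resulting vector rescales F' channel-wise;
#   U'  spatial attention: the channel-mean map of U (1 x H x W) is max
#       pooled (3x3, stride 1), convolved (single k x k, 1 -> 1 channel),
#       multiplied elementwise with the pooled map, and broadcast across all
#       C channels;
#   M   ReLU(U' + F), the residual merge.
# All roles F, F', U, U', M share the shape C x H x W.

#' Attention block parameters
#'
#' @param channel_reduction Bottleneck divisor `r` for the two dense maps of
#'   the channel attention (`C -> C/r -> C`); must divide the channel count
#'   where the block is applied. Default 16.
#' @param spatial_kernel Odd kernel size of the single 1-to-1-channel
#'   convolution in the spatial attention. Default 7.
#' @param n_pre_convs Number of channel-preserving 3x3 conv+BN+ReLU layers
#'   producing F' from the block input. Default 3.
#' @return An object of class `attention_params`.
#' @export
attention_params <- function(channel_reduction = 16L, spatial_kernel = 7L,
                             n_pre_convs = 3L) {
  channel_reduction <- as.integer(channel_reduction)
  spatial_kernel <- as.integer(spatial_kernel)
  n_pre_convs <- as.integer(n_pre_convs)
  if (channel_reduction < 1L) stop("channel_reduction must be >= 1", call. = FALSE)
  if (spatial_kernel < 1L || spatial_kernel %% 2L == 0L) {
    stop("spatial_kernel must be odd", call. = FALSE)
  }
  if (n_pre_convs < 0L) stop("n_pre_convs must be >= 0", call. = FALSE)
  structure(list(channel_reduction = channel_reduction,
                 spatial_kernel = spatial_kernel,
                 n_pre_convs = n_pre_convs),
            class = "attention_params")
}

#' Backbone configuration
#'
#' @param variant `"tiny"` (a two-stage residual net for CPU-scale work:
#'   strided 3->16 stem, stages 16->32->64, all stride 2) or `"resnet50"` (the
#'   standard 4-stage bottleneck layout, widths 256/512/1024/2048).
#' @param insertion_points Integer stages after which a residual attention
#'   block is inserted; default: after every stage.
#' @param pretrained Either `FALSE` (random initialisation; the default and
#'   the only setting exercised by the test-suite) or a path to a saved
#'   parameter tree to warm-start from.
#' @param embedding_dim Per-branch embedding length; defaults to the final
#'   stage width (64 for tiny, 2048 for resnet50). A different value adds a
#'   dense projection after global average pooling.
#' @param dropout_rate Dropout probability in the head; default 0.5.
#' @param head_activation `"sigmoid"` (independent per-class probabilities;
#'   the correct choice for multi-label data and the default) or
#'   `"softmax"`.
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(variant = c("tiny", "resnet50"),
                            insertion_points = NULL,
                            pretrained = FALSE,
                            embedding_dim = NULL,
                            dropout_rate = 0.5,
                            head_activation = c("sigmoid", "softmax")) {
  variant <- match.arg(variant)
  head_activation <- match.arg(head_activation)
  n_stages <- if (variant == "tiny") 2L else 4L
  if (is.null(insertion_points)) insertion_points <- seq_len(n_stages)
  insertion_points <- as.integer(insertion_points)
  if (length(insertion_points) > 0L &&
      (any(insertion_points < 1L) || any(insertion_points > n_stages))) {
    stop(sprintf("insertion_points must reference stages 1..%d", n_stages),
         call. = FALSE)
  }
  final_c <- if (variant == "tiny") 64L else 2048L
  if (is.null(embedding_dim)) embedding_dim <- final_c
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  }
  structure(list(variant = variant,
                 insertion_points = sort(unique(insertion_points)),
                 pretrained = pretrained,
                 embedding_dim = as.integer(embedding_dim),
                 dropout_rate = dropout_rate,
                 head_activation = head_activation,
                 n_stages = n_stages,
                 final_channels = final_c),
            class = "backbone_config")
}

#' Fusion configuration
#'
#' The two eye branches are combined as `p = (1/T) * sum_i w_i * y_i` with
#' `T = 2`, implemented literally (so identical inputs with the default
#' weights (0.5, 0.5) average to half their value; a following dense layer
#' absorbs the scale in the feature modes).
#'
#' @param mode `"feature_average"` (average the branch embeddings, then one
#'   shared head; the default), `"prediction_average"` (one shared head per
#'   eye, then average the predicted values), or `"feature_concat"`
#'   (concatenate embeddings; the head halves the concatenation back to the
#'   class scores and the weights are unused).
#' @param weights Two nonnegative branch weights, default `c(0.5, 0.5)`.
#' @return An object of class `fusion_config` (with `T = 2` branches).
#' @export
fusion_config <- function(mode = c("feature_average", "prediction_average",
                                   "feature_concat"),
                          weights = c(0.5, 0.5)) {
  mode <- match.arg(mode)
  if (length(weights) != 2L || any(weights < 0)) {
    stop("weights must be 2 nonnegative values", call. = FALSE)
  }
  structure(list(T = 2L, weights = as.numeric(weights), mode = mode),
            class = "fusion_config")
}

#' Fuse two per-branch score vectors
#'
#' `p = (1/T) * sum_i w_i * y_i` elementwise for the averaging modes; the
#' concat mode returns the concatenation.
#'
#' @param y_left,y_right Numeric vectors of equal length.
#' @param config A [fusion_config()].
#' @return Fused vector.
#' @export
fuse <- function(y_left, y_right, config = fusion_config()) {
  stopifnot(inherits(config, "fusion_config"))
  if (length(y_left) != length(y_right)) {
    stop("y_left and y_right must have the same length", call. = FALSE)
  }
  if (config$mode == "feature_concat") return(c(y_left, y_right))
  (config$weights[1L] * y_left + config$weights[2L] * y_right) / config$T
}

# ---- initialisation --------------------------------------------------------

init_conv <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

init_bn <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       rmean = rep(0, C), rvar = rep(1, C))
}

init_dense <- function(din, dout) {
  list(W = matrix(stats::rnorm(din * dout, sd = sqrt(2 / din)), din, dout),
       b = rep(0, dout))
}

init_cbr <- function(k, cin, cout) {
  list(conv = list(W = init_conv(k, cin, cout)), bn = init_bn(cout))
}

init_ca <- function(C, r) {
  if (C %% r != 0L) {
    stop(sprintf("channel count %d not divisible by channel_reduction %d",
                 C, r), call. = FALSE)
  }
  h <- C %/% r
  a <- init_dense(C, h); a2 <- init_dense(h, C)
  b <- init_dense(C, h); b2 <- init_dense(h, C)
  # The rectified attention vector must start positive: with zero output
  # biases ReLU(s1 + s2) is frequently all-zero at init, which gates the
  # whole channel-attention path off and stops its gradient permanently.
  # Output biases of 0.5 each start the attention at unit scale.
  a2$b <- rep(0.5, C)
  b2$b <- rep(0.5, C)
  # Same argument one level down: the bottleneck can be as narrow as one
  # unit, so a small positive bias keeps its ReLU from starting all-dead.
  a$b <- rep(0.1, h)
  b$b <- rep(0.1, h)
  list(W1a = a$W, b1a = a$b, W2a = a2$W, b2a = a2$b,
       W1b = b$W, b1b = b$b, W2b = b2$W, b2b = b2$b)
}

init_sa <- function(k) {
  list(W = init_conv(k, 1L, 1L), b = 0)
}

init_ram <- function(C, attn) {
  pre <- lapply(seq_len(attn$n_pre_convs), function(i) init_cbr(3L, C, C))
  if (length(pre) > 0L) names(pre) <- paste0("p", seq_along(pre))
  list(pre = pre,
       ca = init_ca(C, attn$channel_reduction),
       sa = init_sa(attn$spatial_kernel))
}

init_basic_block <- function(cin, cout, stride) {
  p <- list(conv1 = list(W = init_conv(3L, cin, cout)), bn1 = init_bn(cout),
            conv2 = list(W = init_conv(3L, cout, cout)), bn2 = init_bn(cout))
  if (stride != 1L || cin != cout) {
    p$proj <- list(W = init_conv(1L, cin, cout))
    p$bnp <- init_bn(cout)
  }
  p
}

init_bottleneck <- function(cin, cmid, cout, stride) {
  p <- list(conv1 = list(W = init_conv(1L, cin, cmid)), bn1 = init_bn(cmid),
            conv2 = list(W = init_conv(3L, cmid, cmid)), bn2 = init_bn(cmid),
            conv3 = list(W = init_conv(1L, cmid, cout)), bn3 = init_bn(cout))
  if (stride != 1L || cin != cout) {
    p$proj <- list(W = init_conv(1L, cin, cout))
    p$bnp <- init_bn(cout)
  }
  p
}

# Architectural plan: what to build, per variant.
backbone_plan <- function(config) {
  if (config$variant == "tiny") {
    list(stem = list(k = 3L, cin = 3L, cout = 16L, stride = 2L, pad = 1L,
                     pool = FALSE),
         stages = list(
           list(blocks = list(list(kind = "basic", cin = 16L, cout = 32L,
                                   stride = 2L))),
           list(blocks = list(list(kind = "basic", cin = 32L, cout = 64L,
                                   stride = 2L)))))
  } else {
    widths <- c(64L, 128L, 256L, 512L)
    nblocks <- c(3L, 4L, 6L, 3L)
    strides <- c(1L, 2L, 2L, 2L)
    cin <- 64L
    stages <- vector("list", 4L)
    for (s in 1:4) {
      blocks <- vector("list", nblocks[s])
      for (b in seq_len(nblocks[s])) {
        blocks[[b]] <- list(kind = "bottleneck",
                            cin = cin,
                            cmid = widths[s],
                            cout = 4L * widths[s],
                            stride = if (b == 1L) strides[s] else 1L)
        cin <- 4L * widths[s]
      }
      stages[[s]] <- list(blocks = blocks)
    }
    list(stem = list(k = 7L, cin = 3L, cout = 64L, stride = 2L, pad = 3L,
                     pool = TRUE),
         stages = stages)
  }
}

#' Build a single-branch backbone
#'
#' Constructs the branch network — conv+BN+ReLU stem, residual stages,
#' residual attention blocks at the configured insertion points, and global
#' average pooling to the embedding — with seeded random initialisation.
#'
#' @param config A [backbone_config()].
#' @param attention An [attention_params()].
#' @param seed Integer seed; the same seed reproduces identical initial
#'   weights.
#' @return An object of class `bfpc_backbone` holding the parameter tree,
#'   the plan and the configurations.
#' @export
build_backbone <- function(config = backbone_config(),
                           attention = attention_params(),
                           seed = 1L) {
  stopifnot(inherits(config, "backbone_config"),
            inherits(attention, "attention_params"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  plan <- backbone_plan(config)
  params <- list(stem = init_cbr(plan$stem$k, plan$stem$cin, plan$stem$cout))
  params$stages <- lapply(plan$stages, function(st) {
    blocks <- lapply(st$blocks, function(bl) {
      if (bl$kind == "basic") {
        init_basic_block(bl$cin, bl$cout, bl$stride)
      } else {
        init_bottleneck(bl$cin, bl$cmid, bl$cout, bl$stride)
      }
    })
    names(blocks) <- paste0("b", seq_along(blocks))
    list(blocks = blocks)
  })
  names(params$stages) <- paste0("s", seq_along(params$stages))
  params$rams <- list()
  for (ip in config$insertion_points) {
    last <- plan$stages[[ip]]$blocks
    C <- last[[length(last)]]$cout
    params$rams[[paste0("r", ip)]] <- init_ram(C, attention)
  }
  final_c <- plan$stages[[length(plan$stages)]]$blocks
  final_c <- final_c[[length(final_c)]]$cout
  if (config$embedding_dim != final_c) {
    params$embed <- init_dense(final_c, config$embedding_dim)
  }
  if (!isFALSE(config$pretrained)) {
    if (!is.character(config$pretrained) || !file.exists(config$pretrained)) {
      stop("pretrained must be FALSE or the path of a saved parameter tree",
           call. = FALSE)
    }
    params <- readRDS(config$pretrained)
  }
  structure(list(config = config, attention = attention, plan = plan,
                 params = params),
            class = "bfpc_backbone")
}

# ---- composite forward/backward --------------------------------------------

cbr_fwd <- function(x, p, stride, pad, training, keep) {
  cv <- conv_fwd(x, p$conv$W, NULL, stride, pad, keep)
  bn <- bn_fwd(cv$y, p$bn$gamma, p$bn$beta, p$bn$rmean, p$bn$rvar, training,
               keep = keep)
  p$bn$rmean <- bn$rmean
  p$bn$rvar <- bn$rvar
  rl <- relu_fwd(bn$y, keep)
  list(y = rl$y, p = p,
       cache = if (keep) list(cv = cv$cache, bn = bn$cache, rl = rl$cache))
}

cbr_bwd <- function(dy, cache) {
  d1 <- relu_bwd(dy, cache$rl)
  b <- bn_bwd(d1, cache$bn)
  cv <- conv_bwd(b$dx, cache$cv)
  list(dx = cv$dx,
       g = list(conv = list(W = cv$dW),
                bn = list(gamma = b$dgamma, beta = b$dbeta)))
}

basic_block_fwd <- function(x, p, stride, training, keep) {
  c1 <- conv_fwd(x, p$conv1$W, NULL, stride, 1L, keep)
  b1 <- bn_fwd(c1$y, p$bn1$gamma, p$bn1$beta, p$bn1$rmean, p$bn1$rvar,
               training, keep = keep)
  p$bn1$rmean <- b1$rmean; p$bn1$rvar <- b1$rvar
  r1 <- relu_fwd(b1$y, keep)
  c2 <- conv_fwd(r1$y, p$conv2$W, NULL, 1L, 1L, keep)
  b2 <- bn_fwd(c2$y, p$bn2$gamma, p$bn2$beta, p$bn2$rmean, p$bn2$rvar,
               training, keep = keep)
  p$bn2$rmean <- b2$rmean; p$bn2$rvar <- b2$rvar
  if (!is.null(p$proj)) {
    cp <- conv_fwd(x, p$proj$W, NULL, stride, 0L, keep)
    bp <- bn_fwd(cp$y, p$bnp$gamma, p$bnp$beta, p$bnp$rmean, p$bnp$rvar,
                 training, keep = keep)
    p$bnp$rmean <- bp$rmean; p$bnp$rvar <- bp$rvar
    skip <- bp$y
    skip_cache <- if (keep) list(cp = cp$cache, bp = bp$cache)
  } else {
    skip <- x
    skip_cache <- NULL
  }
  ro <- relu_fwd(b2$y + skip, keep)
  list(y = ro$y, p = p,
       cache = if (keep) list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                              c2 = c2$cache, b2 = b2$cache,
                              skip = skip_cache, ro = ro$cache,
                              has_proj = !is.null(p$proj)))
}

basic_block_bwd <- function(dy, cache) {
  dsum <- relu_bwd(dy, cache$ro)
  g <- list()
  b2 <- bn_bwd(dsum, cache$b2)
  g$bn2 <- list(gamma = b2$dgamma, beta = b2$dbeta)
  c2 <- conv_bwd(b2$dx, cache$c2)
  g$conv2 <- list(W = c2$dW)
  d1 <- relu_bwd(c2$dx, cache$r1)
  b1 <- bn_bwd(d1, cache$b1)
  g$bn1 <- list(gamma = b1$dgamma, beta = b1$dbeta)
  c1 <- conv_bwd(b1$dx, cache$c1)
  g$conv1 <- list(W = c1$dW)
  dx <- c1$dx
  if (cache$has_proj) {
    bp <- bn_bwd(dsum, cache$skip$bp)
    g$bnp <- list(gamma = bp$dgamma, beta = bp$dbeta)
    cp <- conv_bwd(bp$dx, cache$skip$cp)
    g$proj <- list(W = cp$dW)
    dx <- dx + cp$dx
  } else {
    dx <- dx + dsum
  }
  list(dx = dx, g = g)
}

bottleneck_fwd <- function(x, p, stride, training, keep) {
  c1 <- conv_fwd(x, p$conv1$W, NULL, 1L, 0L, keep)
  b1 <- bn_fwd(c1$y, p$bn1$gamma, p$bn1$beta, p$bn1$rmean, p$bn1$rvar,
               training, keep = keep)
  p$bn1$rmean <- b1$rmean; p$bn1$rvar <- b1$rvar
  r1 <- relu_fwd(b1$y, keep)
  c2 <- conv_fwd(r1$y, p$conv2$W, NULL, stride, 1L, keep)
  b2 <- bn_fwd(c2$y, p$bn2$gamma, p$bn2$beta, p$bn2$rmean, p$bn2$rvar,
               training, keep = keep)
  p$bn2$rmean <- b2$rmean; p$bn2$rvar <- b2$rvar
  r2 <- relu_fwd(b2$y, keep)
  c3 <- conv_fwd(r2$y, p$conv3$W, NULL, 1L, 0L, keep)
  b3 <- bn_fwd(c3$y, p$bn3$gamma, p$bn3$beta, p$bn3$rmean, p$bn3$rvar,
               training, keep = keep)
  p$bn3$rmean <- b3$rmean; p$bn3$rvar <- b3$rvar
  if (!is.null(p$proj)) {
    cp <- conv_fwd(x, p$proj$W, NULL, stride, 0L, keep)
    bp <- bn_fwd(cp$y, p$bnp$gamma, p$bnp$beta, p$bnp$rmean, p$bnp$rvar,
                 training, keep = keep)
    p$bnp$rmean <- bp$rmean; p$bnp$rvar <- bp$rvar
    skip <- bp$y
    skip_cache <- if (keep) list(cp = cp$cache, bp = bp$cache)
  } else {
    skip <- x
    skip_cache <- NULL
  }
  ro <- relu_fwd(b3$y + skip, keep)
  list(y = ro$y, p = p,
       cache = if (keep) list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                              c2 = c2$cache, b2 = b2$cache, r2 = r2$cache,
                              c3 = c3$cache, b3 = b3$cache,
                              skip = skip_cache, ro = ro$cache,
                              has_proj = !is.null(p$proj)))
}

bottleneck_bwd <- function(dy, cache) {
  dsum <- relu_bwd(dy, cache$ro)
  g <- list()
  b3 <- bn_bwd(dsum, cache$b3)
  g$bn3 <- list(gamma = b3$dgamma, beta = b3$dbeta)
  c3 <- conv_bwd(b3$dx, cache$c3)
  g$conv3 <- list(W = c3$dW)
  d2 <- relu_bwd(c3$dx, cache$r2)
  b2 <- bn_bwd(d2, cache$b2)
  g$bn2 <- list(gamma = b2$dgamma, beta = b2$dbeta)
  c2 <- conv_bwd(b2$dx, cache$c2)
  g$conv2 <- list(W = c2$dW)
  d1 <- relu_bwd(c2$dx, cache$r1)
  b1 <- bn_bwd(d1, cache$b1)
  g$bn1 <- list(gamma = b1$dgamma, beta = b1$dbeta)
  c1 <- conv_bwd(b1$dx, cache$c1)
  g$conv1 <- list(W = c1$dW)
  dx <- c1$dx
  if (cache$has_proj) {
    bp <- bn_bwd(dsum, cache$skip$bp)
    g$bnp <- list(gamma = bp$dgamma, beta = bp$dbeta)
    cp <- conv_bwd(bp$dx, cache$skip$cp)
    g$proj <- list(W = cp$dW)
    dx <- dx + cp$dx
  } else {
    dx <- dx + dsum
  }
  list(dx = dx, g = g)
}

# Channel attention core: input is F' (H, W, N, C).
ca_fwd <- function(x, w, keep) {
  g <- gap_fwd(x)
  z <- g$y
  d1a <- dense_fwd(z, w$W1a, w$b1a, keep)
  r1a <- relu_fwd(d1a$y, keep)
  d2a <- dense_fwd(r1a$y, w$W2a, w$b2a, keep)
  d1b <- dense_fwd(z, w$W1b, w$b1b, keep)
  r1b <- relu_fwd(d1b$y, keep)
  d2b <- dense_fwd(r1b$y, w$W2b, w$b2b, keep)
  rs <- relu_fwd(d2a$y + d2b$y, keep)
  s <- rs$y
  m <- dim(x)[1L] * dim(x)[2L]
  y <- x * rep(as.vector(s), each = m)
  list(y = y,
       cache = if (keep) list(x = x, s = s, gd = g$d,
                              d1a = d1a$cache, r1a = r1a$cache,
                              d2a = d2a$cache, d1b = d1b$cache,
                              r1b = r1b$cache, d2b = d2b$cache,
                              rs = rs$cache, m = m))
}

ca_bwd <- function(dy, cache) {
  m <- cache$m
  d <- dim(cache$x)
  sv <- rep(as.vector(cache$s), each = m)
  dx <- dy * sv
  prod_ <- dy * cache$x
  dim(prod_) <- c(m, d[3L] * d[4L])
  ds <- matrix(colSums(prod_), d[3L], d[4L])
  ds <- relu_bwd(ds, cache$rs)
  ba2 <- dense_bwd(ds, cache$d2a)
  ba1 <- dense_bwd(relu_bwd(ba2$dx, cache$r1a), cache$d1a)
  bb2 <- dense_bwd(ds, cache$d2b)
  bb1 <- dense_bwd(relu_bwd(bb2$dx, cache$r1b), cache$d1b)
  dz <- ba1$dx + bb1$dx
  dx <- dx + gap_bwd(dz, cache$gd)
  g <- list(W1a = ba1$dW, b1a = ba1$db, W2a = ba2$dW, b2a = ba2$db,
            W1b = bb1$dW, b1b = bb1$db, W2b = bb2$dW, b2b = bb2$db)
  list(dx = dx, g = g)
}

# Spatial attention core: input is U (H, W, N, C); output has the same
# shape, the per-location attention product broadcast over channels.
sa_fwd <- function(u, w, keep) {
  d <- dim(u)
  cC <- d[4L]
  mm <- u
  dim(mm) <- c(prod(d[1:3]), cC)
  p0 <- rowMeans(mm)
  dim(p0) <- c(d[1L], d[2L], d[3L], 1L)
  mp <- maxpool_fwd(p0, 3L, 1L, 1L, keep)
  k <- dim(w$W)[1L]
  hp <- (k - 1L) %/% 2L
  # edge-replicate padding keeps the conv dimension-preserving AND constant-
  # preserving (zero padding would darken borders of a constant map)
  cv <- conv_fwd(pad_rep(mp$y, hp), w$W, w$b, 1L, 0L, keep)
  a <- cv$y * mp$y
  y <- rep(as.vector(a), times = cC)
  dim(y) <- d
  list(y = y,
       cache = if (keep) list(mp = mp$cache, cv = cv$cache, P = mp$y,
                              Q = cv$y, d = d))
}

sa_bwd <- function(dy, cache) {
  d <- cache$d
  cC <- d[4L]
  dym <- dy
  dim(dym) <- c(prod(d[1:3]), cC)
  da <- rowSums(dym)
  dim(da) <- c(d[1L], d[2L], d[3L], 1L)
  dq <- da * cache$P
  cv <- conv_bwd(dq, cache$cv)
  k <- dim(cv$dW)[1L]
  dp <- da * cache$Q + pad_rep_bwd(cv$dx, (k - 1L) %/% 2L)
  dp0 <- maxpool_bwd(dp, cache$mp)
  du <- rep(as.vector(dp0) / cC, times = cC)
  dim(du) <- d
  list(dx = du, g = list(W = cv$dW, b = cv$db))
}

# Full residual attention block.
ram_fwd <- function(x, p, training, keep) {
  h <- x
  pre_caches <- vector("list", length(p$pre))
  for (i in seq_along(p$pre)) {
    cb <- cbr_fwd(h, p$pre[[i]], 1L, 1L, training, keep)
    p$pre[[i]] <- cb$p
    pre_caches[[i]] <- cb$cache
    h <- cb$y
  }
  ca <- ca_fwd(h, p$ca, keep)
  sa <- sa_fwd(ca$y, p$sa, keep)
  ro <- relu_fwd(sa$y + x, keep)
  list(y = ro$y, p = p,
       cache = if (keep) list(pre = pre_caches, ca = ca$cache, sa = sa$cache,
                              ro = ro$cache))
}

ram_bwd <- function(dy, cache) {
  dsum <- relu_bwd(dy, cache$ro)
  sa <- sa_bwd(dsum, cache$sa)
  ca <- ca_bwd(sa$dx, cache$ca)
  g <- list(ca = ca$g, sa = sa$g)
  dh <- ca$dx
  gpre <- vector("list", length(cache$pre))
  for (i in rev(seq_along(cache$pre))) {
    cb <- cbr_bwd(dh, cache$pre[[i]])
    gpre[[i]] <- cb$g
    dh <- cb$dx
  }
  if (length(gpre) > 0L) names(gpre) <- paste0("p", seq_along(gpre))
  g$pre <- gpre
  list(dx = dh + dsum, g = g)
}

# Branch forward: images (H, W, N, 3) scaled to [0, 1] -> (N, embedding_dim).
branch_fwd <- function(x, params, plan, config, training, keep) {
  st <- cbr_fwd(x, params$stem, plan$stem$stride, plan$stem$pad, training,
                keep)
  params$stem <- st$p
  h <- st$y
  pool_cache <- NULL
  if (plan$stem$pool) {
    mp <- maxpool_fwd(h, 3L, 2L, 1L, keep)
    pool_cache <- mp$cache
    h <- mp$y
  }
  stage_caches <- vector("list", length(plan$stages))
  ram_caches <- list()
  for (si in seq_along(plan$stages)) {
    blocks <- plan$stages[[si]]$blocks
    bcaches <- vector("list", length(blocks))
    for (bi in seq_along(blocks)) {
      bl <- blocks[[bi]]
      bp <- params$stages[[si]]$blocks[[bi]]
      res <- if (bl$kind == "basic") {
        basic_block_fwd(h, bp, bl$stride, training, keep)
      } else {
        bottleneck_fwd(h, bp, bl$stride, training, keep)
      }
      params$stages[[si]]$blocks[[bi]] <- res$p
      bcaches[[bi]] <- res$cache
      h <- res$y
    }
    stage_caches[[si]] <- bcaches
    rkey <- paste0("r", si)
    if (!is.null(params$rams[[rkey]])) {
      rr <- ram_fwd(h, params$rams[[rkey]], training, keep)
      params$rams[[rkey]] <- rr$p
      ram_caches[[rkey]] <- rr$cache
      h <- rr$y
    }
  }
  gp <- gap_fwd(h)
  emb <- gp$y
  embed_cache <- NULL
  if (!is.null(params$embed)) {
    de <- dense_fwd(emb, params$embed$W, params$embed$b, keep)
    embed_cache <- de$cache
    emb <- de$y
  }
  list(emb = emb, params = params,
       cache = if (keep) list(stem = st$cache, pool = pool_cache,
                              stages = stage_caches, rams = ram_caches,
                              gap = gp$d, embed = embed_cache,
                              plan = plan))
}

branch_bwd <- function(demb, cache, params) {
  g <- list()
  if (!is.null(cache$embed)) {
    de <- dense_bwd(demb, cache$embed)
    g$embed <- list(W = de$dW, b = de$db)
    demb <- de$dx
  }
  dh <- gap_bwd(demb, cache$gap)
  plan <- cache$plan
  g$rams <- list()
  g$stages <- vector("list", length(plan$stages))
  for (si in rev(seq_along(plan$stages))) {
    rkey <- paste0("r", si)
    if (!is.null(cache$rams[[rkey]])) {
      rr <- ram_bwd(dh, cache$rams[[rkey]])
      g$rams[[rkey]] <- rr$g
      dh <- rr$dx
    }
    blocks <- plan$stages[[si]]$blocks
    gb <- vector("list", length(blocks))
    for (bi in rev(seq_along(blocks))) {
      res <- if (blocks[[bi]]$kind == "basic") {
        basic_block_bwd(dh, cache$stages[[si]][[bi]])
      } else {
        bottleneck_bwd(dh, cache$stages[[si]][[bi]])
      }
      gb[[bi]] <- res$g
      dh <- res$dx
    }
    names(gb) <- paste0("b", seq_along(gb))
    g$stages[[si]] <- list(blocks = gb)
  }
  names(g$stages) <- paste0("s", seq_along(g$stages))
  if (!is.null(cache$pool)) dh <- maxpool_bwd(dh, cache$pool)
  st <- cbr_bwd(dh, cache$stem)
  g$stem <- st$g
  list(dx = st$dx, g = g)
}
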