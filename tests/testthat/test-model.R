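# Attention operators, backbone construction, fusion, forward contracts.

test_that("channel attention with zero dense maps is the zero map", {
  p <- attention_params(channel_reduction = 2L)
  w <- channel_attention_weights(4L, p, seed = 1L)
  for (nm in names(w)) w[[nm]] <- w[[nm]] * 0
  f <- array(runif(4 * 5 * 5), c(4, 5, 5))
  u <- channel_attention(f, w, p)
  expect_equal(dim(u), dim(f))
  expect_true(all(u == 0))
})

test_that("channel attention reproduces a hand-computed 2-channel case", {
  # identity bottleneck (r = 1): s = ReLU(2 * ReLU(z)), U = F' * s
  p <- attention_params(channel_reduction = 1L)
  w <- list(W1a = diag(2), b1a = c(0, 0), W2a = diag(2), b2a = c(0, 0),
            W1b = diag(2), b1b = c(0, 0), W2b = diag(2), b2b = c(0, 0))
  f <- array(c(1, 2, 3, 4,      # channel 1, mean 2.5
               5, 6, 7, 8),     # channel 2, mean 6.5
             c(2, 2, 2))
  f <- aperm(f, c(3, 1, 2))     # to C x H x W
  u <- channel_attention(f, w, p)
  expect_equal(u[1, , ], f[1, , ] * 5)    # 2 * mean(channel 1)
  expect_equal(u[2, , ], f[2, , ] * 13)   # 2 * mean(channel 2)
})

test_that("channel attention rejects non-divisible channel counts", {
  p <- attention_params(channel_reduction = 16L)
  f <- array(runif(6 * 4 * 4), c(6, 4, 4))
  expect_error(channel_attention(f, params = p), "divisible")
})

test_that("spatial attention preserves constants and spatial dims", {
  p <- attention_params(spatial_kernel = 3L)
  w <- spatial_attention_weights(p, seed = 2L)
  f <- array(3, c(4, 6, 6))
  u <- spatial_attention(f, w, p)
  expect_equal(dim(u), dim(f))
  # constant input: channel mean 3, max pool 3, conv gives 3*sum(W)+b,
  # product is constant and identical across channels
  q <- 3 * sum(w$W) + w$b
  expect_equal(u, array(q * 3, dim(f)), tolerance = 1e-12)
})

test_that("spatial attention matches hand arithmetic on a 3x3 map", {
  p <- attention_params(spatial_kernel = 3L)
  w <- list(W = array(0, c(3, 3, 1, 1)), b = 0.5)
  w$W[2, 2, 1, 1] <- 2            # centre-tap-only kernel
  vals <- matrix(c(1, 2, 3,
                   4, 5, 6,
                   7, 8, 9), 3, 3, byrow = TRUE)
  f <- array(vals, c(1, 3, 3))    # already 1 x H x W; channel mean = itself
  u <- spatial_attention(f, w, p)
  # 3x3 stride-1 max pool (edge windows reduced over valid pixels)
  mp <- matrix(c(5, 6, 6,
                 8, 9, 9,
                 8, 9, 9), 3, 3, byrow = TRUE)
  expect_equal(u[1, , ], (2 * mp + 0.5) * mp, tolerance = 1e-12)
  expect_error(attention_params(spatial_kernel = 4L), "odd")
})

test_that("the residual block is ReLU(U' + F) and matches staged oracles", {
  p <- attention_params(channel_reduction = 2L, spatial_kernel = 3L,
                        n_pre_convs = 0L)
  w <- residual_attention_weights(4L, p, seed = 3L)
  w$pre <- list()
  f <- array(rnorm(4 * 5 * 5), c(4, 5, 5))
  # staged: F -> U -> U' -> ReLU(U' + F) through the public single ops
  u <- channel_attention(f, w$ca, p)
  up <- spatial_attention(u, w$sa, p)
  m_staged <- pmax(up + f, 0)
  m_block <- residual_attention_block(f, w, p)
  expect_equal(m_block, m_staged, tolerance = 1e-12)
  # zero spatial conv forces U' = 0, so the block is plain ReLU(F)
  w0 <- w
  w0$sa$W <- w0$sa$W * 0
  w0$sa$b <- 0
  expect_equal(residual_attention_block(f, w0, p), pmax(f, 0),
               tolerance = 1e-12)
})

test_that("attention blocks preserve shape across random geometries", {
  set.seed(11)
  p <- attention_params(channel_reduction = 2L, spatial_kernel = 3L,
                        n_pre_convs = 1L)
  for (i in 1:5) {
    C <- sample(c(2L, 4L, 6L), 1)
    H <- sample(4:9, 1)
    W <- sample(4:9, 1)
    f <- array(rnorm(C * H * W), c(C, H, W))
    w <- residual_attention_weights(C, p, seed = i)
    expect_equal(dim(channel_attention(f, w$ca, p)), c(C, H, W))
    u <- channel_attention(f, w$ca, p)
    expect_equal(dim(spatial_attention(u, w$sa, p)), c(C, H, W))
    expect_equal(dim(residual_attention_block(f, w, p)), c(C, H, W))
  }
})

test_that("fuse implements the literal weighted sliding average", {
  yl <- runif(8)
  yr <- runif(8)
  cfg <- fusion_config()
  # identical inputs with the default weights halve the value
  expect_equal(fuse(yl, yl, cfg), 0.5 * yl)
  # weights (2, 0) recover the left input exactly
  expect_equal(fuse(yl, yr, fusion_config(weights = c(2, 0))), yl)
  # brute-force elementwise oracle
  w <- c(0.3, 0.9)
  got <- fuse(yl, yr, fusion_config(weights = w))
  oracle <- sapply(1:8, function(k) (w[1] * yl[k] + w[2] * yr[k]) / 2)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_error(fuse(yl, yr[1:4]), "length")
  expect_error(fusion_config(weights = c(-1, 1)), "nonnegative")
})

test_that("build_backbone honours the seed and validates insertion points", {
  cfg <- backbone_config("tiny")
  b1 <- build_backbone(cfg, seed = 5L)
  b2 <- build_backbone(cfg, seed = 5L)
  expect_identical(b1$params, b2$params)
  b3 <- build_backbone(cfg, seed = 6L)
  expect_false(identical(b1$params, b3$params))
  expect_error(backbone_config("tiny", insertion_points = 3L), "stages 1..2")
  expect_error(backbone_config("tiny", dropout_rate = 1), "dropout")
})

test_that("the tiny branch produces the configured embedding shape", {
  bb <- build_backbone(backbone_config("tiny"), seed = 1L)
  x <- array(runif(64 * 64 * 2 * 3), c(64, 64, 2, 3))
  out <- bfpcnet:::branch_fwd(x, bb$params, bb$plan, bb$config, training = FALSE,
                    keep = FALSE)
  expect_equal(dim(out$emb), c(2L, 64L))
  expect_true(all(is.finite(out$emb)))
})

test_that("forward respects the head activation contracts", {
  ds <- make_dataset(n = 2L, size = 32L, seed = 21L)
  rec <- ds$records
  imgs <- lapply(seq_len(2), function(i) {
    lapply(c("left_image", "right_image"), function(cl) {
      weighted_enhance(normalize_image(
        read_image(file.path(ds$dir, rec[[cl]][i])), 32L))
    })
  })
  bb <- build_backbone(backbone_config("tiny"), seed = 2L)
  m_sig <- bfpcnet:::new_bfpc_model(bb, fusion_config(), seed = 2L)
  pr <- forward_pair(m_sig, imgs[[1]][[1]], imgs[[1]][[2]])
  expect_length(pr, 8L)
  expect_named(pr, c("N", "D", "G", "C", "A", "H", "M", "O"))
  expect_true(all(pr >= 0 & pr <= 1))
  bb_soft <- build_backbone(backbone_config("tiny",
                                            head_activation = "softmax"),
                            seed = 2L)
  m_soft <- bfpcnet:::new_bfpc_model(bb_soft, fusion_config(), seed = 2L)
  ps <- forward_pair(m_soft, imgs[[1]][[1]], imgs[[1]][[2]])
  expect_equal(sum(ps), 1, tolerance = 1e-6)
  # shared branches + symmetric fusion weights: swapping eyes is a no-op
  swapped <- forward_pair(m_sig, imgs[[1]][[2]], imgs[[1]][[1]])
  expect_equal(pr, swapped, tolerance = 1e-10)
})

test_that("zeroed attention degrades to an attention-free backbone", {
  bb <- build_backbone(backbone_config("tiny"), seed = 9L)
  zeroed <- bb$params
  for (rk in names(zeroed$rams)) {
    for (nm in names(zeroed$rams[[rk]]$ca)) {
      zeroed$rams[[rk]]$ca[[nm]] <- zeroed$rams[[rk]]$ca[[nm]] * 0
    }
    zeroed$rams[[rk]]$sa$W <- zeroed$rams[[rk]]$sa$W * 0
    zeroed$rams[[rk]]$sa$b <- 0
  }
  bare <- build_backbone(backbone_config("tiny", insertion_points = integer()),
                         seed = 9L)
  # identical residual weights in both networks
  bare$params$stem <- bb$params$stem
  bare$params$stages <- bb$params$stages
  x <- array(runif(64 * 64 * 2 * 3), c(64, 64, 2, 3))
  e1 <- bfpcnet:::branch_fwd(x, zeroed, bb$plan, bb$config, training = FALSE,
                   keep = FALSE)$emb
  e2 <- bfpcnet:::branch_fwd(x, bare$params, bare$plan, bare$config, training = FALSE,
                   keep = FALSE)$emb
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("gradient reaches every trainable parameter on a synthetic batch", {
  set.seed(31)
  # bottleneck width > 1 (channel_reduction 4): a width-1 ReLU bottleneck
  # can be legitimately dead at initialisation on one batch
  bb <- build_backbone(backbone_config("tiny"),
                       attention_params(channel_reduction = 4L), seed = 31L)
  m <- bfpcnet:::new_bfpc_model(bb, fusion_config(), seed = 31L)
  n <- 8L
  spec <- synthetic_spec(n_patients = n, image_size = 64L, seed = 3L,
                         class_probabilities = c(0, rep(0.4, 7)))
  xl <- array(0, c(64, 64, n, 3))
  xr <- array(0, c(64, 64, n, 3))
  y <- matrix(0L, n, 8L)
  for (i in seq_len(n)) {
    pat <- generate_patient(spec, i - 1L)
    xl[, , i, ] <- pat$left
    xr[, , i, ] <- pat$right
    y[i, ] <- as.integer(pat$record[, c("N", "D", "G", "C", "A", "H", "M",
                                        "O")])
  }
  out <- bfpcnet:::model_fwd(m, xl, xr, training = TRUE, keep = TRUE)
  cfg <- train_config(image_size = 64L)
  lg <- bfpcnet:::batch_loss_grad(out, smooth_labels(y, 0.1), m, cfg)
  g <- bfpcnet:::model_bwd(m, lg$dz, out$cache)$g
  fl <- bfpcnet:::param_flatten(g)
  fl <- fl[!grepl("(rmean|rvar)$", names(fl))]
  dead <- names(fl)[vapply(fl, function(a) all(a == 0), logical(1))]
  expect_length(dead, 0L)
})

test_that("the resnet50 variant runs a 256x256 forward without shape errors", {
  bb <- build_backbone(backbone_config("resnet50"), seed = 1L)
  x <- array(runif(256 * 256 * 1 * 3), c(256, 256, 1, 3))
  out <- bfpcnet:::branch_fwd(x, bb$params, bb$plan, bb$config, training = FALSE,
                    keep = FALSE)
  expect_equal(dim(out$emb), c(1L, 2048L))
  expect_true(all(is.finite(out$emb)))
})
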