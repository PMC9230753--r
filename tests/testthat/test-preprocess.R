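# Image normalisation, the weighted Gaussian enhancement, and augmentation.

const_img <- function(v, h = 48L, w = 48L) array(v, c(h, w, 3L))

test_that("normalize_image preserves constants and hits the target size", {
  img <- const_img(77, 100L, 60L)
  out <- normalize_image(img, 48L)
  expect_equal(dim(out), c(48L, 48L, 3L))
  expect_true(all(abs(out - 77) < 1e-9))
  # default size is 256
  expect_equal(dim(normalize_image(const_img(1, 64L, 64L))), c(256L, 256L, 3L))
  expect_error(normalize_image(img, 16L), "32")
  expect_error(normalize_image(array(1, c(10, 10)), 48L), "RGB")
  expect_error(normalize_image(array(1, c(0, 10, 3)), 48L), "empty")
})

test_that("integer-factor downscaling equals block averaging", {
  set.seed(1)
  img <- array(runif(512 * 512 * 3, 0, 255), c(512, 512, 3))
  # checkerboard pattern on channel 1 for a structured case
  img[, , 1] <- 255 * ((outer(1:512, 1:512, "+")) %% 2)
  out <- normalize_image(img, 256L)
  oracle <- array(0, c(256, 256, 3))
  for (ch in 1:3) {
    for (i in 1:256) {
      for (j in 1:256) {
        oracle[i, j, ch] <- mean(img[(2 * i - 1):(2 * i),
                                     (2 * j - 1):(2 * j), ch])
      }
    }
  }
  expect_equal(out, oracle, tolerance = 1e-12)
})

test_that("gaussian_kernel is normalised, symmetric and matches the formula", {
  k <- gaussian_kernel(enhance_params())
  expect_equal(dim(k), c(63L, 63L))
  expect_true(all(k > 0))
  expect_lt(abs(sum(k) - 1), 1e-9)
  expect_equal(k, k[63:1, ])
  expect_equal(k, k[, 63:1])
  # direct evaluation for a 3x3, sigma = 10 case
  k3 <- gaussian_kernel(enhance_params(kernel_h = 3L, kernel_w = 3L,
                                       sigma = 10))
  ref <- outer(-1:1, -1:1, function(dy, dx) exp(-(dx^2 + dy^2) / (2 * 100)))
  ref <- ref / sum(ref)
  expect_equal(k3, ref, tolerance = 1e-12)
  expect_error(enhance_params(kernel_h = 4L), "odd")
  expect_error(enhance_params(sigma = 0), "sigma")
})

test_that("weighted enhancement maps every constant image to uniform 128", {
  for (v in c(0, 1, 37, 100, 128, 200, 254.5, 255)) {
    out <- weighted_enhance(const_img(v))
    expect_true(all(abs(out - 128) < 1e-8), info = paste("constant", v))
  }
})

test_that("enhancement of an impulse matches a dense-convolution oracle", {
  p <- enhance_params()
  s <- 81L
  img <- const_img(0, s, s)
  img[41, 41, ] <- 255
  out <- weighted_enhance(img, p)
  # oracle: explicit spatial convolution with reflective borders, then the
  # affine combination and clip
  kern <- gaussian_kernel(p)
  refl <- function(idx, n) {
    while (any(idx < 1L | idx > n)) {
      idx[idx < 1L] <- 1L - idx[idx < 1L]
      idx[idx > n] <- 2L * n + 1L - idx[idx > n]
    }
    idx
  }
  ch <- img[, , 1]
  blur <- matrix(0, s, s)
  for (ki in 1:63) {
    for (kj in 1:63) {
      rows <- refl(seq_len(s) + ki - 32L, s)
      cols <- refl(seq_len(s) + kj - 32L, s)
      blur <- blur + kern[ki, kj] * ch[rows, cols]
    }
  }
  oracle <- pmin(pmax(4 * ch - 4 * blur + 128, 0), 255)
  expect_equal(out[, , 1], oracle, tolerance = 1e-9)
  expect_equal(out[, , 2], oracle, tolerance = 1e-9)  # channels independent
})

test_that("enhancement commutes with flips on the interior", {
  set.seed(4)
  img <- array(runif(80 * 80 * 3, 0, 255), c(80, 80, 3))
  p <- enhance_params()
  fh <- augment_op("flip_horizontal")
  a <- weighted_enhance(apply_augment(img, fh), p)
  b <- apply_augment(weighted_enhance(img, p), fh)
  interior <- 32:49  # 31-pixel margin for the 63-tap kernel
  expect_equal(a[interior, interior, ], b[interior, interior, ],
               tolerance = 1e-9)
  fv <- augment_op("flip_vertical")
  a <- weighted_enhance(apply_augment(img, fv), p)
  b <- apply_augment(weighted_enhance(img, p), fv)
  expect_equal(a[interior, interior, ], b[interior, interior, ],
               tolerance = 1e-9)
})

test_that("augmentation ops form the expected group", {
  set.seed(2)
  img <- array(runif(20 * 20 * 3), c(20, 20, 3))
  fh <- augment_op("flip_horizontal")
  fv <- augment_op("flip_vertical")
  r90 <- augment_op("rotate", 90L)
  expect_identical(apply_augment(apply_augment(img, fh), fh), img)
  expect_identical(apply_augment(apply_augment(img, fv), fv), img)
  out <- img
  for (i in 1:4) out <- apply_augment(out, r90)
  expect_identical(out, img)
  expect_identical(apply_augment(img, augment_op("rotate", 180L)),
                   apply_augment(apply_augment(img, fh), fv))
  expect_error(augment_op("rotate", 45L), "90")
  expect_error(apply_augment(img, list(kind = "rotate")), "augment_op")
})

test_that("balance_dataset tops classes up to their targets", {
  rec <- make_records(matrix(rep(c(0L, 0L, 1L, rep(0L, 5)), each = 284),
                             284, 8))
  out <- balance_dataset(rec, c(G = 1638L), seed = 9L)
  expect_equal(sum(out$G), 1638L)
  expect_true(all(rec$id %in% out$id))            # originals conserved
  expect_equal(sum(out$provenance == "augmented"), 1638L - 284L)
  expect_true(all(nzchar(out$aug_ops[out$provenance == "augmented"])))
  # class already at target: untouched
  expect_identical(balance_dataset(rec, c(G = 100L), seed = 9L), rec)
  # reproducible op log
  out2 <- balance_dataset(rec, c(G = 1638L), seed = 9L)
  expect_identical(out$aug_ops, out2$aug_ops)
  out3 <- balance_dataset(rec, c(G = 1638L), seed = 10L)
  expect_false(identical(out$aug_ops, out3$aug_ops))
})

test_that("balance_dataset errors on empty classes and supports downsampling", {
  rec <- make_records(random_labels(40, seed = 2))
  rec$H <- 0L
  rec$N <- as.integer(rowSums(rec[, c("D", "G", "C", "A", "H", "M", "O")]) == 0)
  expect_error(balance_dataset(rec, c(H = 10L)), "empty")
  nd <- sum(rec$D)
  if (nd > 3L) {
    down <- balance_dataset(rec, targets = integer(),
                            downsample = c(D = 3L), seed = 1L)
    expect_equal(sum(down$D), 3L)
  }
})
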