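# Image preprocessing: normalisation, weighted Gaussian enhancement,
# and pixel-exact geometric augmentation.
#
# Convention used throughout the package: an image is a numeric array of
# dimension (height, width, 3), RGB channel order, intensities in [0, 255],
# 0-based pixel semantics only at file boundaries (PNG I/O rescales to the
# png package's [0, 1]).

#' Enhancement parameters
#'
#' Parameters of the image-weighted enhancement
#' `I_weight = alpha * I_org + beta * blur(I_org) + gamma`, where `blur` is
#' Gaussian blurring with an `kernel_h` x `kernel_w` kernel of standard
#' deviation `sigma` pixels (identical in both directions). The defaults
#' (`alpha = 4`, `beta = -4`, `gamma = 128`, 63 x 63 kernel, `sigma = 10`)
#' subtract the low-frequency background and re-centre residuals at
#' mid-grey, which flattens uneven illumination and highlights vessels and
#' lesions in retinal photographs.
#'
#' @param alpha Scalar weight on the original image.
#' @param beta Scalar weight on the blurred image.
#' @param gamma Additive offset, in 8-bit intensity units.
#' @param kernel_h,kernel_w Odd, positive kernel extents in pixels.
#' @param sigma Gaussian standard deviation in pixels; must be positive.
#' @return An object of class `enhance_params`.
#' @examples
#' p <- enhance_params()
#' img <- array(100, c(40, 40, 3))
#' all(weighted_enhance(img, p) == 128)
#' @export
enhance_params <- function(alpha = 4, beta = -4, gamma = 128,
                           kernel_h = 63L, kernel_w = 63L, sigma = 10) {
  kernel_h <- as.integer(kernel_h)
  kernel_w <- as.integer(kernel_w)
  if (kernel_h <= 0L || kernel_w <= 0L || kernel_h %% 2L == 0L ||
      kernel_w %% 2L == 0L) {
    stop("kernel_h and kernel_w must be odd positive integers", call. = FALSE)
  }
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("sigma must be positive", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 kernel_h = kernel_h, kernel_w = kernel_w, sigma = sigma),
            class = "enhance_params")
}

#' Normalised 2-D Gaussian kernel
#'
#' Evaluates `exp(-(dx^2 + dy^2) / (2 sigma^2))` on the integer grid centred
#' at the kernel midpoint and normalises the entries to sum to one.
#'
#' @param params An [enhance_params()] object (only the kernel fields are
#'   used).
#' @return A `kernel_h` x `kernel_w` matrix with positive entries summing
#'   to 1, symmetric under horizontal and vertical reflection.
#' @export
gaussian_kernel <- function(params = enhance_params()) {
  stopifnot(inherits(params, "enhance_params"))
  gh <- gaussian_profile(params$kernel_h, params$sigma)
  gw <- gaussian_profile(params$kernel_w, params$sigma)
  outer(gh, gw)
}

# 1-D normalised Gaussian profile; the 2-D kernel is its outer product,
# which makes the blur exactly separable.
gaussian_profile <- function(k, sigma) {
  d <- seq_len(k) - (k + 1) / 2
  g <- exp(-d * d / (2 * sigma * sigma))
  g / sum(g)
}

# Dense banded operator applying a 1-D kernel along an axis of length n with
# reflective (mirror-without-repeat, "symmetric with edge") border handling.
# Row i of the matrix holds the kernel taps re-routed through reflection.
blur_operator <- function(n, kernel) {
  k <- length(kernel)
  half <- (k - 1L) %/% 2L
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    src <- i + (seq_len(k) - 1L) - half
    src <- reflect_index(src, n)
    for (j in seq_len(k)) {
      B[i, src[j]] <- B[i, src[j]] + kernel[j]
    }
  }
  B
}

# Reflect out-of-range indices into 1..n (edge pixels repeated: 0 -> 1,
# -1 -> 2, n+1 -> n, ...). Applied iteratively so kernels wider than the
# image remain valid.
reflect_index <- function(idx, n) {
  repeat {
    low <- idx < 1L
    idx[low] <- 1L - idx[low]
    high <- idx > n
    idx[high] <- 2L * n + 1L - idx[high]
    if (!any(idx < 1L | idx > n)) return(idx)
  }
}

# Separable Gaussian blur of one channel (matrix) with reflective borders.
blur_channel <- function(ch, params) {
  gh <- gaussian_profile(params$kernel_h, params$sigma)
  gw <- gaussian_profile(params$kernel_w, params$sigma)
  Br <- blur_operator(nrow(ch), gh)
  Bc <- blur_operator(ncol(ch), gw)
  Br %*% ch %*% t(Bc)
}

#' Image-weighted enhancement
#'
#' Per channel computes `alpha * I + beta * blur(I) + gamma` and clips the
#' result to `[0, 255]`. The blur is the separable Gaussian of
#' [gaussian_kernel()] with reflective border handling, so a constant image
#' maps to a uniform image of value `gamma` under the defaults
#' (`4 c - 4 c + 128 = 128`).
#'
#' @param image Numeric `(H, W, 3)` array in `[0, 255]`.
#' @param params An [enhance_params()] object.
#' @return Enhanced `(H, W, 3)` array in `[0, 255]`.
#' @export
weighted_enhance <- function(image, params = enhance_params()) {
  if (!inherits(params, "enhance_params")) {
    stop("params must be an enhance_params object", call. = FALSE)
  }
  check_rgb(image)
  out <- array(0, dim(image))
  for (ch in 1:3) {
    i_org <- image[, , ch]
    i_blur <- blur_channel(i_org, params)
    out[, , ch] <- params$alpha * i_org + params$beta * i_blur + params$gamma
  }
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

check_rgb <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] != 3L) {
    stop("image must be an (H, W, 3) RGB array", call. = FALSE)
  }
  if (any(dim(image)[1:2] == 0L)) {
    stop("image is empty", call. = FALSE)
  }
  invisible(image)
}

#' Resize an RGB image to a square target
#'
#' Resamples to `size` x `size`. Downscaling uses pixel-area averaging
#' (each output pixel is the area-weighted mean of the source pixels it
#' covers; at integer factors this is exact block averaging), upscaling uses
#' bilinear interpolation. Aspect ratio is not preserved: both axes are
#' resampled to `size` independently, which matches how square-input
#' classifiers consume pre-cropped fundus photographs.
#'
#' @param image Numeric `(H, W, 3)` array in `[0, 255]`.
#' @param size Target edge length in pixels, at least 32.
#' @return `(size, size, 3)` array in `[0, 255]`.
#' @export
normalize_image <- function(image, size = 256L) {
  check_rgb(image)
  size <- as.integer(size)
  if (size < 32L) stop("size must be at least 32 pixels", call. = FALSE)
  d <- dim(image)
  Wr <- resample_operator(d[1L], size)
  Wc <- resample_operator(d[2L], size)
  out <- array(0, c(size, size, 3L))
  for (ch in 1:3) {
    out[, , ch] <- Wr %*% image[, , ch] %*% t(Wc)
  }
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

# Linear resampling operator n_in -> n_out: area averaging when shrinking,
# bilinear (pixel-centre aligned) when enlarging. Rows sum to 1, so constants
# are preserved exactly.
resample_operator <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  if (n_out <= n_in) {
    scale <- n_in / n_out
    for (i in seq_len(n_out)) {
      lo <- (i - 1) * scale
      hi <- i * scale
      j0 <- floor(lo) + 1L
      j1 <- ceiling(hi)
      for (j in j0:min(j1, n_in)) {
        ov <- min(hi, j) - max(lo, j - 1)
        if (ov > 0) W[i, j] <- ov / scale
      }
    }
  } else {
    scale <- n_in / n_out
    for (i in seq_len(n_out)) {
      src <- (i - 0.5) * scale + 0.5   # position in source pixel-centre units
      j0 <- floor(src)
      frac <- src - j0
      jl <- min(max(j0, 1L), n_in)
      jr <- min(max(j0 + 1L, 1L), n_in)
      W[i, jl] <- W[i, jl] + (1 - frac)
      W[i, jr] <- W[i, jr] + frac
    }
  }
  W
}

#' Augmentation operation
#'
#' A pixel-exact geometric transform: rotation by a multiple of 90 degrees,
#' horizontal (left/right) flip, or vertical (up/down) flip. Restricting
#' rotation to the 90-degree group keeps augmentation invertible and free of
#' interpolation, and class labels are unchanged by every op.
#'
#' @param kind One of `"rotate"`, `"flip_horizontal"`, `"flip_vertical"`.
#' @param angle_degrees Rotation amount, one of 90, 180, 270 (rotate only).
#' @return An object of class `augment_op`.
#' @export
augment_op <- function(kind = c("rotate", "flip_horizontal", "flip_vertical"),
                       angle_degrees = 90L) {
  kind <- match.arg(kind)
  angle_degrees <- as.integer(angle_degrees)
  if (kind == "rotate" && !angle_degrees %in% c(90L, 180L, 270L)) {
    stop("angle_degrees must be one of 90, 180, 270", call. = FALSE)
  }
  structure(list(kind = kind, angle_degrees = angle_degrees),
            class = "augment_op")
}

#' Apply an augmentation operation to an image
#'
#' @param image Numeric `(H, W, 3)` array.
#' @param op An [augment_op()].
#' @return Transformed image array.
#' @export
apply_augment <- function(image, op) {
  if (!inherits(op, "augment_op")) stop("op must be an augment_op", call. = FALSE)
  check_rgb(image)
  switch(op$kind,
    flip_horizontal = image[, rev(seq_len(dim(image)[2L])), , drop = FALSE],
    flip_vertical = image[rev(seq_len(dim(image)[1L])), , , drop = FALSE],
    rotate = {
      out <- image
      for (i in seq_len(op$angle_degrees %/% 90L)) out <- rotate90_once(out)
      out
    },
    stop("unsupported augmentation kind", call. = FALSE)
  )
}

# 90 degrees counter-clockwise: (i, j) -> (W - j + 1, i).
rotate90_once <- function(image) {
  d <- dim(image)
  out <- array(0, c(d[2L], d[1L], d[3L]))
  for (ch in seq_len(d[3L])) {
    out[, , ch] <- t(image[, , ch])[rev(seq_len(d[2L])), , drop = FALSE]
  }
  out
}

# Encode/decode op logs ("rot90", "fliph", "flipv") used by record
# provenance and the balancing module.
augment_op_from_code <- function(code) {
  switch(code,
    rot90 = augment_op("rotate", 90L),
    rot180 = augment_op("rotate", 180L),
    rot270 = augment_op("rotate", 270L),
    fliph = augment_op("flip_horizontal"),
    flipv = augment_op("flip_vertical"),
    stop(sprintf("unknown augment code '%s'", code), call. = FALSE)
  )
}

augment_codes <- c("rot90", "rot180", "rot270", "fliph", "flipv")

# ---- PNG I/O ---------------------------------------------------------------

#' Read an RGB image from a PNG or JPEG-free path
#'
#' Reads a PNG file into the package's `(H, W, 3)` `[0, 255]` convention.
#' Grayscale files are rejected (retinal photographs are colour images and
#' the enhancement operates per colour channel).
#'
#' @param path File path of a PNG image.
#' @return `(H, W, 3)` numeric array in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    stop(sprintf("grayscale image rejected: %s", path), call. = FALSE)
  }
  if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write an RGB image to a PNG file
#'
#' @param image `(H, W, 3)` numeric array in `[0, 255]`.
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_image <- function(image, path) {
  check_rgb(image)
  img <- image / 255
  img[img < 0] <- 0
  img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}
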