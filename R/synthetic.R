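# Deterministic synthetic paired fundus-like images.
#
# The generator emulates the layout of ODIR-style data: per patient, one
# left and one right RGB photograph plus a multi-hot 8-class label vector
# (N, D, G, C, A, H, M, O). Images are circular bright discs on a dark
# background; each active disease label adds one documented, visually
# well-separated motif so that small classifiers can learn the classes from
# pixels alone:
#
#   D  small bright yellow blobs (microaneurysm-like dots)
#   G  enlarged pale inner disc with a crisp white rim (cup enlargement)
#   C  global milky haze plus fine white granules over the whole frame
#   A  dark blue round spots inside the disc
#   H  a pair of crossing bright green lines (vessel-crossing cue)
#   M  a dark magenta tilted crescent at the disc rim
#   O  bright cyan pixel speckle inside the disc
#
#   N  no motif at all; set exactly when no disease bit is active
#
# Hues are deliberately unique per motif (yellow/white/blue/green/magenta)
# so classes stay separable after the background-subtracting enhancement;
# the catalogue is a learnability fixture, not lesion morphology.
#
# Rendering is a pure function of (spec, patient index): each patient draws
# from an RNG stream seeded by an integer mix of the dataset seed and the
# patient index, so patient i is reproducible independently of n_patients.

label_names <- function() c("N", "D", "G", "C", "A", "H", "M", "O")

#' Specification for a synthetic paired-fundus dataset
#'
#' @param n_patients Number of patients (each contributes two images).
#' @param image_size Square image edge in pixels; at least 32.
#' @param class_probabilities Eight values in `[0, 1]`, one per label in the
#'   order N, D, G, C, A, H, M, O. Entries 2..8 are per-eye Bernoulli rates
#'   for the seven disease motifs. The first (N) entry is accepted for shape
#'   compatibility with the label vector but ignored: N is derived by label
#'   closure (N = 1 exactly when no disease bit is active).
#' @param seed Integer seed controlling labels and rendering.
#' @param per_eye_independence If `TRUE` (default), the left and right eye
#'   draw disease bits independently, as in real paired data where the two
#'   eyes may carry different diseases; if `FALSE` both eyes share one draw.
#'   The patient-level label is always the union (logical OR) of the two
#'   per-eye label sets.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_patients = 20L,
                           image_size = 64L,
                           class_probabilities = c(0, rep(0.10, 7)),
                           seed = 1L,
                           per_eye_independence = TRUE) {
  n_patients <- as.integer(n_patients)
  image_size <- as.integer(image_size)
  if (n_patients <= 0L) stop("n_patients must be positive", call. = FALSE)
  if (length(image_size) != 1L || image_size < 32L) {
    stop("image_size must be a single square edge of at least 32 pixels",
         call. = FALSE)
  }
  if (length(class_probabilities) != 8L ||
      any(class_probabilities < 0) || any(class_probabilities > 1)) {
    stop("class_probabilities must be 8 values in [0, 1]", call. = FALSE)
  }
  structure(list(n_patients = n_patients,
                 image_size = image_size,
                 class_probabilities = as.numeric(class_probabilities),
                 seed = as.integer(seed),
                 per_eye_independence = isTRUE(per_eye_independence)),
            class = "synthetic_spec")
}

# 32-bit integer mix of (seed, index); keeps results in [0, 2^31).
patient_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 16807 + 12345) %% 2147483647
}

#' Generate one synthetic patient
#'
#' @param spec A [synthetic_spec()].
#' @param index Patient index, `0 <= index < n_patients`.
#' @return A list with `record` (one-row data frame: id, left_image,
#'   right_image, the eight 0/1 labels, provenance) and the two rendered
#'   `(size, size, 3)` images `left` and `right`.
#' @export
generate_patient <- function(spec, index) {
  stopifnot(inherits(spec, "synthetic_spec"))
  index <- as.integer(index)
  if (index < 0L || index >= spec$n_patients) {
    stop("index out of range", call. = FALSE)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(patient_seed(spec$seed, index))

  p <- spec$class_probabilities[-1L]   # disease rates D..O
  bits_left <- as.integer(stats::runif(7L) < p)
  bits_right <- if (spec$per_eye_independence) {
    as.integer(stats::runif(7L) < p)
  } else {
    bits_left
  }
  left <- render_eye(spec$image_size, bits_left)
  right <- render_eye(spec$image_size, bits_right)
  bits <- as.integer(bits_left | bits_right)
  labels <- c(as.integer(sum(bits) == 0L), bits)
  id <- sprintf("p%05d", index)
  record <- data.frame(id = id,
                       left_image = paste0(id, "_left.png"),
                       right_image = paste0(id, "_right.png"),
                       stringsAsFactors = FALSE)
  for (k in 1:8) record[[label_names()[k]]] <- labels[k]
  record$provenance <- "original"
  record$aug_ops <- ""
  list(record = record, left = left, right = right)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Render a single eye: dark background, bright disc, one motif per active
# disease bit (large-area motifs G, C, M first, then A, H, D, O on top).
render_eye <- function(size, bits) {
  s <- size
  img <- array(0, c(s, s, 3L))
  gx <- matrix(rep(seq_len(s), each = s), s, s)        # column index
  gy <- matrix(rep(seq_len(s), times = s), s, s)       # row index
  cx <- (s + 1) / 2
  cy <- (s + 1) / 2
  r <- 0.42 * s
  d2 <- (gx - cx)^2 + (gy - cy)^2
  disc <- d2 <= r * r
  fall <- pmax(0, 1 - d2 / (r * r))                    # radial falloff
  base <- c(205, 125, 60)                              # fundus orange
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[disc] <- base[ch] * (0.55 + 0.45 * fall[disc])
    img[, , ch] <- plane
  }
  img <- img + array(6 * stats::runif(s * s), c(s, s, 3L))  # sensor noise

  paint_disc <- function(img, px, py, pr, col, alpha = 1) {
    m <- (gx - px)^2 + (gy - py)^2 <= pr * pr
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[m] <- (1 - alpha) * plane[m] + alpha * col[ch]
      img[, , ch] <- plane
    }
    img
  }
  rnd_in_disc <- function(margin = 0.6) {
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- sqrt(stats::runif(1)) * r * margin
    c(cx + rad * cos(ang), cy + rad * sin(ang))
  }

  # large-area motifs render first so the small high-frequency motifs
  # (dots, lines, speckle) are never occluded by haze or disc fills
  if (bits[2L] == 1L) {                                # G: pale inner disc
    img <- paint_disc(img, cx, cy, 0.22 * s, c(245, 235, 215), alpha = 0.9)
    ring <- abs(sqrt(d2) - 0.22 * s) <= max(1, 0.012 * s)
    for (ch in 1:3) {                                  # crisp white rim
      plane <- img[, , ch]
      plane[ring] <- 255
      img[, , ch] <- plane
    }
  }
  if (bits[3L] == 1L) {                                # C: global milky haze
    img <- 0.5 * img + 0.5 * 215
    # fine granular clouding over the WHOLE frame (also outside the disc),
    # the high-frequency signature that survives background subtraction
    pick <- which(stats::runif(s * s) < 0.04)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[pick] <- plane[pick] + 70
      img[, , ch] <- plane
    }
  }
  if (bits[6L] == 1L) {                                # M: dark crescent
    ang <- stats::runif(1, 0, 2 * pi)
    ox <- cx + 0.18 * s * cos(ang)
    oy <- cy + 0.18 * s * sin(ang)
    m <- disc & ((gx - ox)^2 + (gy - oy)^2 > (0.36 * s)^2)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[m] <- c(150, 15, 150)[ch]
      img[, , ch] <- plane
    }
  }
  if (bits[4L] == 1L) {                                # A: dark spots
    na_ <- sample(3:5, 1L)
    for (i in seq_len(na_)) {
      pos <- rnd_in_disc()
      img <- paint_disc(img, pos[1L], pos[2L], max(1.8, 0.055 * s),
                        c(20, 20, 170))
    }
  }
  if (bits[5L] == 1L) {                                # H: crossing lines
    pos <- rnd_in_disc(0.4)
    a1 <- stats::runif(1, 0, pi)
    a2 <- a1 + stats::runif(1, pi / 4, 3 * pi / 4)
    for (a in c(a1, a2)) {
      dist <- abs((gx - pos[1L]) * sin(a) - (gy - pos[2L]) * cos(a))
      m <- dist <= max(1.5, 0.02 * s) & disc
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[m] <- c(60, 255, 120)[ch]
        img[, , ch] <- plane
      }
    }
  }
  if (bits[1L] == 1L) {                                # D: bright blobs
    nb <- sample(6:9, 1L)
    for (i in seq_len(nb)) {
      pos <- rnd_in_disc(0.75)
      img <- paint_disc(img, pos[1L], pos[2L], max(2, 0.05 * s),
                        c(255, 245, 60))
    }
  }
  if (bits[7L] == 1L) {                                # O: cyan speckle
    idx <- which(disc)
    pick <- sample(idx, max(10L, round(0.02 * length(idx))))
    col <- c(0, 235, 255)
    # 2x2 blocks rather than single pixels so the specks survive the first
    # stride-2 convolution intact
    pi_ <- ((pick - 1L) %% s) + 1L
    pj_ <- ((pick - 1L) %/% s) + 1L
    pi2 <- pmin(pi_ + 1L, s)
    pj2 <- pmin(pj_ + 1L, s)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[cbind(pi_, pj_)] <- col[ch]
      plane[cbind(pi2, pj_)] <- col[ch]
      plane[cbind(pi_, pj2)] <- col[ch]
      plane[cbind(pi2, pj2)] <- col[ch]
      img[, , ch] <- plane
    }
  }
  img[img < 0] <- 0
  img[img > 255] <- 255
  img
}

#' Generate and write a synthetic dataset
#'
#' Writes `n_patients` left/right PNG pairs plus a CSV manifest with header
#' `id,left_image,right_image,N,D,G,C,A,H,M,O` to `out_dir`. Refuses to
#' overwrite an existing manifest.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Writable output directory (created if missing).
#' @return Path of the written manifest, invisibly.
#' @export
generate_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  if (file.exists(manifest_path)) {
    stop(sprintf("manifest already exists: %s (refusing to overwrite)",
                 manifest_path), call. = FALSE)
  }
  records <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    pat <- generate_patient(spec, i - 1L)
    write_image(pat$left, file.path(out_dir, pat$record$left_image))
    write_image(pat$right, file.path(out_dir, pat$record$right_image))
    records[[i]] <- pat$record
  }
  records <- do.call(rbind, records)
  write_manifest(records, manifest_path)
  invisible(manifest_path)
}
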