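# ODIR-style manifest handling and the 4/1 stratified split.
#
# A manifest is a CSV with header id,left_image,right_image,N,D,G,C,A,H,M,O;
# labels are 0/1 and ordered N (normal), D (diabetes), G (glaucoma),
# C (cataract), A (age-related macular degeneration), H (hypertension),
# M (pathological myopia), O (other). Labels are patient-level: both eyes
# share the row's label vector.

manifest_columns <- function() {
  c("id", "left_image", "right_image", label_names())
}

#' Read and validate an ODIR-style manifest
#'
#' Rows with unresolvable image files or non-binary labels are not fatal:
#' they are collected into a validation-error report attached as the
#' `"errors"` attribute (see [manifest_errors()]) and the valid rows are
#' returned. A missing or wrong header is a hard error.
#'
#' @param path CSV manifest path.
#' @param image_dir Directory against which relative image paths resolve;
#'   defaults to the manifest's directory.
#' @param check_files If `TRUE` (default), rows whose image files do not
#'   exist are rejected into the error report.
#' @return A data frame of patient records (columns id, left_image,
#'   right_image, the eight labels, provenance, aug_ops) with attributes
#'   `image_dir` and `errors`.
#' @export
read_manifest <- function(path, image_dir = dirname(path),
                          check_files = TRUE) {
  if (!file.exists(path)) {
    stop(sprintf("manifest not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- manifest_columns()
  if (!all(need %in% names(df))) {
    stop(sprintf("manifest is missing required columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  errors <- data.frame(row = integer(), id = character(),
                       problem = character(), stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(df))
  for (k in label_names()) {
    v <- df[[k]]
    bad <- !(v %in% c("0", "1"))
    if (any(bad)) {
      errors <- rbind(errors, data.frame(
        row = which(bad), id = df$id[bad],
        problem = sprintf("label %s not in {0,1}", k),
        stringsAsFactors = FALSE))
      keep[bad] <- FALSE
    }
    df[[k]] <- suppressWarnings(as.integer(v))
  }
  if (check_files && nrow(df) > 0L) {
    for (col in c("left_image", "right_image")) {
      pth <- file.path(image_dir, df[[col]])
      bad <- !file.exists(pth) & keep
      if (any(bad)) {
        errors <- rbind(errors, data.frame(
          row = which(bad), id = df$id[bad],
          problem = sprintf("missing file in %s", col),
          stringsAsFactors = FALSE))
        keep[bad] <- FALSE
      }
    }
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (is.null(out$provenance)) out$provenance <- rep("original", nrow(out))
  if (is.null(out$aug_ops)) out$aug_ops <- rep("", nrow(out))
  attr(out, "image_dir") <- image_dir
  attr(out, "errors") <- errors
  out
}

#' Validation errors collected by [read_manifest()]
#' @param records A record data frame returned by [read_manifest()].
#' @return Data frame of soft-rejected rows (row, id, problem).
#' @export
manifest_errors <- function(records) {
  attr(records, "errors") %||%
    data.frame(row = integer(), id = character(), problem = character())
}

#' Write a manifest CSV
#'
#' @param records Record data frame (as produced by [read_manifest()] or
#'   [generate_dataset()]).
#' @param path Destination CSV path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(records, path) {
  utils::write.csv(records[, manifest_columns(), drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Train/test split counts for one class
#'
#' Applies the 4/1 split rule: for a class pool of size `n`, the test count
#' is `round(n * (1 - train_ratio))` (nearest integer, ties to even — R's
#' `round`) and the train count is the remainder. This nearest-integer rule
#' is the unique simple rounding consistent with the published per-class
#' train/test tallies this package regression-tests against (574.6 rounds up
#' to 575, 151.2 rounds down to 151).
#'
#' @param n Class pool size.
#' @param train_ratio Training fraction in (0, 1); default 4/5.
#' @return Named integer vector `c(train, test)`.
#' @export
split_counts <- function(n, train_ratio = 4 / 5) {
  if (train_ratio <= 0 || train_ratio >= 1) {
    stop("train_ratio must be in (0, 1)", call. = FALSE)
  }
  test <- as.integer(round(n * (1 - train_ratio)))
  c(train = as.integer(n) - test, test = test)
}

#' Stratified 4/1 train/test split of patient records
#'
#' Records are pooled per class (a multi-label record belongs to every class
#' it carries); classes are processed rarest-first and each class draws its
#' `round(n_c * (1 - train_ratio))` test records at random from its not yet
#' assigned members. A record already assigned through an earlier class
#' keeps its assignment, so no patient ever appears on both sides
#' (multi-label leakage guard).
#'
#' @param records Record data frame.
#' @param train_ratio Training fraction, default 4/5.
#' @param seed Integer seed for the draw.
#' @return List with data frames `train` and `test` and a `counts` data
#'   frame of per-class pool/train/test sizes.
#' @export
split_records <- function(records, train_ratio = 4 / 5, seed = 1L) {
  if (train_ratio <= 0 || train_ratio >= 1) {
    stop("train_ratio must be in (0, 1)", call. = FALSE)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- nrow(records)
  assign_ <- rep(NA_character_, n)
  sizes <- vapply(label_names(), function(k) sum(records[[k]] == 1L),
                  integer(1L))
  for (k in names(sort(sizes))) {
    pool <- which(records[[k]] == 1L)
    if (length(pool) == 0L) next
    want_test <- split_counts(length(pool), train_ratio)[["test"]]
    have_test <- sum(assign_[pool] == "test", na.rm = TRUE)
    free <- pool[is.na(assign_[pool])]
    take <- max(0L, min(length(free), want_test - have_test))
    test_pick <- if (take > 0L) sample(free, take) else integer()
    assign_[test_pick] <- "test"
    assign_[setdiff(free, test_pick)] <- "train"
  }
  assign_[is.na(assign_)] <- "train"
  counts <- data.frame(
    class = label_names(),
    n = sizes,
    train = vapply(label_names(), function(k)
      sum(records[[k]] == 1L & assign_ == "train"), integer(1L)),
    test = vapply(label_names(), function(k)
      sum(records[[k]] == 1L & assign_ == "test"), integer(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  train <- records[assign_ == "train", , drop = FALSE]
  test <- records[assign_ == "test", , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  for (d in list(train, test)) attr(d, "image_dir") <- attr(records, "image_dir")
  attr(train, "image_dir") <- attr(records, "image_dir")
  attr(test, "image_dir") <- attr(records, "image_dir")
  list(train = train, test = test, counts = counts)
}

#' Published ODIR-2019 class distribution
#'
#' The per-class image tallies of the ODIR-2019 benchmark as published with
#' the binocular classifier this package implements: original image counts,
#' counts after augmentation-driven balancing ("preprocessed"), and the
#' 4/1 train/test tallies. Used as the regression target for
#' [split_counts()] and for the dataset-level arithmetic (6392 images in
#' total; 44.95% normal, 55.05% diseased, 25.16% diabetic retinopathy).
#'
#' @return Data frame with columns class, original, preprocessed, train,
#'   test.
#' @export
odir_class_counts <- function() {
  data.frame(
    class = c("N", "D", "G", "C", "A", "H", "M", "O"),
    original = c(2873L, 1608L, 284L, 293L, 266L, 128L, 232L, 708L),
    preprocessed = c(2873L, 1539L, 1638L, 1674L, 1560L, 756L, 1206L, 1346L),
    train = c(2298L, 1231L, 1310L, 1339L, 1248L, 605L, 965L, 1077L),
    test = c(575L, 308L, 328L, 335L, 312L, 151L, 241L, 269L),
    stringsAsFactors = FALSE)
}

#' Write a split to disk
#'
#' Writes `train.csv`, `test.csv` and a JSON summary of per-class counts.
#'
#' @param split Result of [split_records()].
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_split <- function(split, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- write_manifest(split$train, file.path(out_dir, "train.csv"))
  p2 <- write_manifest(split$test, file.path(out_dir, "test.csv"))
  p3 <- file.path(out_dir, "split_counts.json")
  jsonlite::write_json(split$counts, p3, dataframe = "rows")
  invisible(c(p1, p2, p3))
}
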