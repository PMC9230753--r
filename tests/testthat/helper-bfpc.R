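# Shared fixtures: small synthetic datasets built in code at test time.

make_dataset <- function(n = 8L, size = 64L, seed = 1L,
                         probs = c(0, rep(0.10, 7)), dir = NULL) {
  dir <- dir %||% withr::local_tempdir(.local_envir = parent.frame())
  spec <- synthetic_spec(n_patients = n, image_size = size,
                         class_probabilities = probs, seed = seed)
  manifest <- generate_dataset(spec, dir)
  list(spec = spec, dir = dir, manifest = manifest,
       records = read_manifest(manifest))
}

# Record data frame without any image files (for split/balance logic).
make_records <- function(labels, id_prefix = "r") {
  labels <- as.matrix(labels)
  colnames(labels) <- c("N", "D", "G", "C", "A", "H", "M", "O")
  df <- data.frame(id = sprintf("%s%04d", id_prefix, seq_len(nrow(labels))),
                   left_image = "l.png", right_image = "r.png",
                   stringsAsFactors = FALSE)
  for (k in colnames(labels)) df[[k]] <- as.integer(labels[, k])
  df$provenance <- "original"
  df$aug_ops <- ""
  df
}

# Multi-hot label matrix with one class forced on per row, others random.
random_labels <- function(n, seed = 1L, p = 0.2) {
  set.seed(seed)
  m <- matrix(rbinom(n * 7L, 1L, p), n, 7L)
  cbind(as.integer(rowSums(m) == 0L), m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
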