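# Augmentation-driven class balancing.
#
# Under-represented classes are topped up by cloning existing records of the
# class with a randomly drawn pixel-exact augmentation (90/180/270-degree
# rotation, horizontal or vertical flip); the op is applied identically to
# both eyes when images are materialised, preserving the left/right pairing.
# Each clone records its op chain in `aug_ops`, so a balanced dataset is
# reproducible from the originals plus the log.

#' Balance per-class record counts by augmentation
#'
#' For every class named in `targets` whose pool is smaller than its target,
#' clones of seeded-randomly chosen member records (with random augmentation
#' ops) are appended until the class count reaches the target. Classes at or
#' above target are left untouched unless an explicit `downsample` target is
#' given, in which case a seeded random subset of that class's records is
#' kept. Every original record id survives at least once unless removed by
#' an explicit downsample.
#'
#' @param records Record data frame.
#' @param targets Named integer vector of per-class minimum counts, e.g.
#'   `c(G = 1638, H = 756)`. Names must be labels N,D,G,C,A,H,M,O.
#' @param seed Integer seed; fixes the clone/op sequence.
#' @param downsample Optional named integer vector of per-class maximum
#'   counts; surplus records of those classes are dropped at random. The
#'   reduction rule is a generic seeded subsample, exposed because published
#'   class tallies sometimes shrink during preprocessing without a stated
#'   rule.
#' @return Augmented record data frame; clones carry
#'   `provenance = "augmented"` and an op code in `aug_ops`.
#' @export
balance_dataset <- function(records, targets, seed = 1L, downsample = NULL) {
  bad <- setdiff(names(targets), label_names())
  if (length(bad) > 0L) {
    stop(sprintf("unknown class in targets: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  if (!is.null(downsample)) {
    for (k in names(downsample)) {
      pool <- which(records[[k]] == 1L)
      excess <- length(pool) - downsample[[k]]
      if (excess > 0L) {
        drop <- sample(pool, excess)
        records <- records[-drop, , drop = FALSE]
      }
    }
  }

  clones <- list()
  clone_n <- 0L
  for (k in names(targets)) {
    pool <- which(records[[k]] == 1L)
    need <- targets[[k]] - length(pool) -
      sum(vapply(clones, function(r) r[[k]], integer(1L)) == 1L)
    if (length(pool) == 0L && targets[[k]] > 0L) {
      stop(sprintf("class %s is empty; cannot augment to %d", k, targets[[k]]),
           call. = FALSE)
    }
    while (need > 0L) {
      src <- records[sample(pool, 1L), , drop = FALSE]
      op <- sample(augment_codes, 1L)
      clone_n <- clone_n + 1L
      src$id <- sprintf("%s_aug%04d", src$id, clone_n)
      src$provenance <- "augmented"
      src$aug_ops <- if (nzchar(src$aug_ops)) paste0(src$aug_ops, "+", op) else op
      clones[[length(clones) + 1L]] <- src
      if (src[[k]] == 1L) need <- need - 1L
    }
  }
  out <- rbind(records, do.call(rbind, clones))
  rownames(out) <- NULL
  attr(out, "image_dir") <- attr(records, "image_dir")
  out
}
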