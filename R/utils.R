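# Internal helpers shared across modules.

# Derive a child seed from a master seed; keeps results reproducible while
# staying inside the 32-bit integer range R requires for set.seed().
.childSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647L)
}

# Rank-based (Mann-Whitney) ROC AUC with midrank tie handling.  Scores need
# only be an ordering; any strictly monotone transform leaves the AUC
# unchanged.  Cross-checked against pROC in the test suite.
.aucRank <- function(scores, positive) {
  positive <- as.logical(positive)
  npos <- as.numeric(sum(positive))  # doubles: rank sums overflow int32
  nneg <- as.numeric(sum(!positive))
  if (npos == 0L || nneg == 0L) {
    stop("AUC needs at least one positive and one negative observation")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# Stratified k-fold assignment: samples of each class are shuffled and dealt
# round-robin so every fold carries both classes in near-equal proportion.
.stratifiedFolds <- function(labels, k, seed) {
  if (k < 2L) stop("k must be at least 2")
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

.assertChoice <- function(x, choices, what) {
  if (!all(x %in% choices)) {
    stop(sprintf("invalid %s: %s (must be one of %s)", what,
                 paste(setdiff(x, choices), collapse = ", "),
                 paste(choices, collapse = ", ")))
  }
  invisible(x)
}
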