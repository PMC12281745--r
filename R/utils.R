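# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

#' Derive a reproducible sub-seed from a root seed
#'
#' Stages of the pipeline draw from named substreams so that one root seed
#' fans out deterministically and re-running a single stage reproduces its
#' output. Kept below 2^31 so it is always a valid R integer seed.
#'
#' @param seed integer root seed.
#' @param offset integer substream index (>= 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset) * 16807) %% 2147483629L)
}

# Stratified fold assignment: every fold gets a near-equal share of each
# class. Returns an integer vector of fold ids in 1..k.
stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Tiny FNV-1a content hash over a serialized object; used for cohort /
# split provenance checks (training vs validation disjointness audits).
content_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  # drop serialization header (R version stamp) so hashes are stable
  bytes <- as.integer(bytes[-seq_len(14)])
  m <- 2147483647            # 2^31 - 1; keeps everything in integer range
  h <- 17
  for (b in bytes) h <- (h * 257 + b) %% m
  sprintf("%08x", h)
}

# Pooled-SD standardized mean difference (Cohen's d), group1 minus group0.
cohens_d <- function(x1, x0) {
  n1 <- length(x1); n0 <- length(x0)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n0 - 1) * stats::var(x0)) / (n1 + n0 - 2)
  if (!is.finite(sp2) || sp2 <= 0) return(NA_real_)
  (mean(x1) - mean(x0)) / sqrt(sp2)
}
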