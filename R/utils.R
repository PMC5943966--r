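# Internal helpers: reproducible seed streams and train-fold standardization.

# Derive a child seed from a root seed and one or more integer stream indices.
# Lehmer-style multiplicative chaining modulo the Mersenne prime 2^31 - 1; all
# intermediates stay below 2^53 so double arithmetic is exact, and the result
# always fits a 32-bit R integer. The scheme is fixed so that full runs are
# bit-reproducible from a single root seed.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in idx) {
    s <- (s * 48271 + as.double(i) + 1) %% 2147483647
  }
  as.integer(s)
}

# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's RNG
# state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else if
      (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Column means and standard deviations for z-scoring. Constant columns get
# scale 1 so they map to all-zero columns instead of NaN; a zero column cannot
# contribute to a linear-SVM decision, so its weight is exactly 0 and feature
# index bookkeeping stays intact.
zscore_fit <- function(x) {
  n <- nrow(x)
  ctr <- colMeans(x)
  scl <- sqrt(pmax(colSums(x^2) - n * ctr^2, 0) / (n - 1))
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

zscore_apply <- function(x, fit) {
  n <- nrow(x)
  (x - rep(fit$center, each = n)) / rep(fit$scale, each = n)
}

# Stratified fold assignment: within each class, samples are shuffled under
# the given seed and dealt round-robin into d folds, so per-fold class counts
# differ by at most one sample from exact proportionality.
stratified_folds <- function(y, d, seed) {
  y <- as.factor(y)
  if (d < 2) stop("number of folds must be at least 2", call. = FALSE)
  if (d > min(table(y))) {
    stop("number of folds (", d, ") exceeds the smallest class size (",
         min(table(y)), ")", call. = FALSE)
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(d), length(idx))
    }
  })
  folds
}

# First index attaining the maximum; strict-improvement semantics mean ties
# are won by the earliest iteration (the larger feature subset).
argmax_first <- function(v) which.max(v)

# Last index attaining the maximum: update-on->= semantics, ties won by the
# latest iteration (the smaller feature subset).
argmax_last <- function(v) length(v) - which.max(rev(v)) + 1L
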