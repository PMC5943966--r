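# Naive double-loop oracle for the overlap statistics, kept deliberately
# independent of the package implementation: explicit pairwise distances,
# explicit neighbour sort, explicit counts, then the defining formulas.
naive_overlap <- function(x, y, k) {
  x <- as.matrix(x)
  y <- as.character(y)
  n <- nrow(x)
  tab <- table(y)
  diff_count <- integer(n)
  or <- numeric(n)
  for (i in seq_len(n)) {
    dists <- numeric(n)
    for (j in seq_len(n)) {
      dists[j] <- sqrt(sum((x[i, ] - x[j, ])^2))
    }
    ord <- setdiff(order(dists), i)  # stable: ties to the lower index
    nbrs <- ord[seq_len(k)]
    diff_count[i] <- sum(y[nbrs] != y[i])
    or[i] <- sum(y != y[i]) / n
  }
  r <- diff_count / k - or
  list(diff_count = diff_count, or = or, r = r, nr = r / or,
       average_nr = mean(r / or))
}

# Independent elimination-schedule oracle: the floor-with-minimum-one rule
# applied arithmetically, never through the package's functions.
naive_schedule <- function(m, t) {
  sizes <- integer(0)
  while (m > 0) {
    sizes <- c(sizes, m)
    m <- m - max(1, floor(t * m))
  }
  sizes
}
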