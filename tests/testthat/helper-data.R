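# Small dataset builders shared across test files.

random_dataset <- function(n, m, n_classes = 2, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * m), n, m)
  # guarantee >= 2 samples per class
  y <- factor(c(rep(seq_len(n_classes), each = 2),
                sample(n_classes, n - 2 * n_classes, replace = TRUE)))
  list(x = x, y = y)
}

# Two well-separated Gaussian blobs: centroid distance delta * sqrt(q) >>
# within-class spread, so every neighbourhood is pure.
separable_blobs <- function(n_per_class = c(15, 15), m = 30, q = 5,
                            seed = 1) {
  simulate_hdlss(n_per_class = n_per_class, m = m, q = q, delta = 8,
                 label_noise = 0, seed = seed)
}

write_demo_tsv <- function(path, labels = c("A", "A", "B", "B")) {
  writeLines(c(
    "sample\tlabel\tg1\tg2\tg3",
    paste("s1", labels[1], "0.1", "1.0", "5.0", sep = "\t"),
    paste("s2", labels[2], "0.2", "0.9", "5.1", sep = "\t"),
    paste("s3", labels[3], "1.1", "0.2", "4.9", sep = "\t"),
    paste("s4", labels[4], "1.3", "0.1", "5.2", sep = "\t")
  ), path)
  path
}
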