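#' Simulate a high-dimension small-sample classification dataset
#'
#' Generates a labeled sample-by-feature matrix in the regime typical of
#' microarray benchmarks — tens of samples, hundreds to thousands of
#' features, 2 to 5 classes — with a controllable number of informative
#' features, class separation, class imbalance and planted label noise.
#' Every feature is unit-variance Gaussian noise; the `q` informative
#' features (drawn at random and recorded as ground truth) additionally
#' receive class-specific mean offsets, equally spaced with spacing `delta`
#' and centred at zero, so adjacent class means differ by `delta` standard
#' deviations on every informative feature. With `label_noise = rho > 0`,
#' `round(rho * n)` samples drawn uniformly have their label reassigned to a
#' uniformly random *other* class, planting samples that sit in the wrong
#' class's region — exactly the contamination the screening selector is
#' designed to set aside.
#'
#' The Gaussian class-conditional model is chosen as the fixture model
#' because its separability has closed-form limits useful for verification
#' (e.g. the single-feature Bayes accuracy is `pnorm(delta / 2)`); it is not
#' a claim about real microarray noise.
#'
#' @param n_per_class Integer vector of per-class sample counts (2 to 5
#'   classes, each with at least 2 samples).
#' @param m Total number of features.
#' @param q Number of informative features, `0 <= q <= m`.
#' @param delta Class-mean spacing on informative features, in standard
#'   deviation units.
#' @param label_noise Fraction `rho` in `[0, 0.5)` of samples whose label is
#'   flipped to a random other class.
#' @param seed Integer seed; the same spec and seed reproduce the identical
#'   dataset.
#' @return A `labeled_dataset` with extra components `informative`
#'   (character vector of ground-truth informative feature names), `y_clean`
#'   (the labels before noise) and `spec` (the generating parameters).
#' @examples
#' sim <- simulate_hdlss(n_per_class = c(30, 30), m = 200, q = 10,
#'                       delta = 2, label_noise = 0.1, seed = 42)
#' table(sim$y, sim$y_clean)
#' sim$informative
#' @export
simulate_hdlss <- function(n_per_class = c(30, 30), m = 2000, q = 10,
                           delta = 2, label_noise = 0, seed = 1) {
  n_per_class <- as.integer(n_per_class)
  nc <- length(n_per_class)
  if (nc < 2L || nc > 5L) stop("2 to 5 classes supported", call. = FALSE)
  if (any(n_per_class < 2L)) {
    stop("every class needs at least 2 samples", call. = FALSE)
  }
  if (q > m) stop("q must not exceed m", call. = FALSE)
  if (label_noise < 0 || label_noise >= 0.5) {
    stop("label_noise must lie in [0, 0.5)", call. = FALSE)
  }
  n <- sum(n_per_class)
  class_names <- paste0("c", seq_len(nc))
  y_clean <- factor(rep(class_names, n_per_class), levels = class_names)
  offsets <- delta * (seq_len(nc) - (nc + 1) / 2)

  with_seed(seed, {
    x <- matrix(stats::rnorm(n * m), n, m)
    informative <- if (q > 0) sort(sample.int(m, q)) else integer(0)
    for (j in informative) {
      x[, j] <- x[, j] + offsets[as.integer(y_clean)]
    }
    y <- y_clean
    n_flip <- round(label_noise * n)
    if (n_flip > 0) {
      flip <- sample.int(n, n_flip)
      for (i in flip) {
        others <- setdiff(seq_len(nc), as.integer(y_clean[i]))
        y[i] <- class_names[others[sample.int(length(others), 1L)]]
      }
    }
  })

  rownames(x) <- paste0("S", seq_len(n))
  colnames(x) <- paste0("f", seq_len(m))
  ds <- new_labeled_dataset(x, y)
  ds$informative <- colnames(x)[informative]
  ds$y_clean <- y_clean
  ds$spec <- list(n_per_class = n_per_class, m = m, q = q, delta = delta,
                  label_noise = label_noise, seed = seed)
  ds
}
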