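#' k-nearest-neighbour indices on a feature subspace
#'
#' Brute-force exact Euclidean nearest neighbours of every sample among the
#' other samples, on the full feature set or a subspace. At the sample sizes
#' this package targets (tens to a few hundred samples) exact pairwise
#' distances are fast and avoid any approximation.
#'
#' @param x Numeric matrix, samples in rows.
#' @param k Neighbourhood size, `1 <= k <= nrow(x) - 1`.
#' @param features Optional feature subset (column indices or names);
#'   default all columns.
#' @return Integer matrix with `nrow(x)` rows and `k` columns; row `i` holds
#'   the indices of the `k` nearest other samples of sample `i`, closest
#'   first. A sample is never its own neighbour. Distance ties are broken by
#'   ascending sample index (file order), so the result is deterministic.
#' @examples
#' x <- matrix(c(0, 1, 10), ncol = 1)
#' knn_indices(x, k = 1)
#' @export
knn_indices <- function(x, k, features = NULL) {
  x <- as.matrix(x)
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  n <- nrow(x)
  if (ncol(x) < 1L) stop("feature subset must be non-empty", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k >= n) {
    stop("k must satisfy 1 <= k <= n - 1 (k = ", k, ", n = ", n, ")",
         call. = FALSE)
  }
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  out <- matrix(0L, n, k)
  idx <- seq_len(n)
  for (i in idx) {
    # order() is stable here: equal distances resolve to the lower index
    out[i, ] <- order(d[i, ], idx)[seq_len(k)]
  }
  out
}

#' Baseline heterogeneous-sample ratio OR(x)
#'
#' For each sample, the fraction of all training samples that belong to a
#' different class. This is the chance level against which a neighbourhood's
#' heterogeneous fraction is compared: OR(x) depends only on the class of
#' `x`, never on its position in feature space.
#'
#' @param y Class labels (factor or coercible).
#' @return Numeric vector, one value in (0, 1) per sample.
#' @export
baseline_ratio <- function(y) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L) {
    stop("baseline ratio undefined for single-class data", call. = FALSE)
  }
  n <- length(y)
  tab <- table(y)
  as.numeric((n - tab[as.character(y)]) / n)
}

#' Per-sample class-overlap profile on a feature subspace
#'
#' Quantifies, for every training sample, how much it mixes with samples of
#' other classes on a given feature subspace. For sample x with k nearest
#' neighbours, let Difflabel(x) be the number of those neighbours with a
#' different class label and OR(x) the dataset-wide heterogeneous fraction
#' for x's class. The raw overlap degree is
#'
#'   r(x) = Difflabel(x) / k - OR(x)
#'
#' and its normalized form is
#'
#'   Nr(x) = r(x) / OR(x).
#'
#' Nr(x) = -1 means a pure same-class neighbourhood; Nr(x) > 0 means the
#' neighbourhood holds more heterogeneous samples than chance, i.e. x lies
#' in a class-overlap region. The average of Nr over the dataset measures how
#' separable the classes are on the subspace: it approaches -1 for cleanly
#' separated classes and concentrates near 0 when labels carry no spatial
#' signal. Neighbourhoods are recomputed on the given subspace — overlap is a
#' property of the subspace, not of the full feature set.
#'
#' @param x Numeric matrix (samples x features) or a `labeled_dataset`.
#' @param y Class labels (ignored when `x` is a `labeled_dataset`).
#' @param k Neighbourhood size (the field-standard default is 9).
#' @param features Optional feature subset; default all.
#' @return An `overlap_profile`: a data frame with one row per sample and
#'   columns `label`, `diff_count` (heterogeneous neighbours, 0..k), `or`
#'   (baseline ratio), `r`, and `nr`, with attributes `k`, `features` and
#'   `average_nr` (mean of `nr` over all samples).
#' @examples
#' sim <- simulate_hdlss(n_per_class = c(15, 15), m = 20, q = 5, delta = 6)
#' prof <- overlap_profile(sim$x, sim$y, k = 5)
#' average_overlap(prof)   # near -1: the classes are well separated
#' @seealso [average_overlap()], [screen_overlapping_samples()]
#' @export
overlap_profile <- function(x, y = NULL, k = 9, features = NULL) {
  if (inherits(x, "labeled_dataset")) {
    y <- x$y
    x <- x$x
  }
  x <- as.matrix(x)
  y <- as.factor(y)
  or <- baseline_ratio(y)
  nn <- knn_indices(x, k, features)
  ycode <- as.integer(y)
  diff_count <- as.integer(rowSums(matrix(ycode[nn], nrow(nn),
                                          ncol(nn)) != ycode))
  r <- diff_count / k - or
  nr <- r / or
  prof <- data.frame(label = as.character(y), diff_count = diff_count,
                     or = or, r = r, nr = nr,
                     row.names = rownames(x) %||% seq_len(nrow(x)),
                     stringsAsFactors = FALSE)
  structure(prof, k = k, features = features, average_nr = mean(nr),
            class = c("overlap_profile", "data.frame"))
}

#' Average normalized overlap degree
#'
#' Arithmetic mean of Nr(x) over all samples of a profile or over a sample
#' subset — the subset form is what the screening selector uses to score a
#' feature subset after setting aside heavily overlapping samples.
#'
#' @param profile An `overlap_profile`.
#' @param subset Optional vector of sample indices; default all samples.
#' @return A single number.
#' @export
average_overlap <- function(profile, subset = NULL) {
  stopifnot(inherits(profile, "overlap_profile"))
  if (is.null(subset)) return(mean(profile$nr))
  if (length(subset) == 0L) stop("sample subset must be non-empty",
                                 call. = FALSE)
  mean(profile$nr[subset])
}

#' @export
print.overlap_profile <- function(x, ...) {
  cat("Overlap profile:", nrow(x), "samples, k =", attr(x, "k"), "\n")
  cat("average Nr(x):", format(attr(x, "average_nr"), digits = 4), "\n")
  cat("samples with Nr(x) > 0:", sum(x$nr > 0), "\n")
  invisible(x)
}
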