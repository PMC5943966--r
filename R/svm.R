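# Linear-SVM training, per-feature weight scores and stratified CV accuracy.
# All SVMs in the package are linear-kernel C-SVC machines from libsvm (via
# e1071); multi-class problems use libsvm's one-vs-one decomposition.

# Decompose a fitted e1071 linear svm into its one-vs-one weight vectors.
# Returns a machines x features matrix (one row for the binary case).
pairwise_weights <- function(model) {
  nc <- model$nclasses
  nSV <- model$nSV
  SV <- model$SV
  co <- model$coefs
  start <- c(1L, cumsum(nSV) + 1L)[seq_len(nc)]
  npair <- nc * (nc - 1L) / 2L
  W <- matrix(0, npair, ncol(SV))
  p <- 0L
  for (i in seq_len(nc - 1L)) {
    for (j in seq.int(i + 1L, nc)) {
      p <- p + 1L
      ii <- seq.int(start[i], length.out = nSV[i])
      jj <- seq.int(start[j], length.out = nSV[j])
      W[p, ] <- colSums(co[ii, j - 1L] * SV[ii, , drop = FALSE]) +
        colSums(co[jj, i] * SV[jj, , drop = FALSE])
    }
  }
  W
}

train_linear_svm <- function(x, y, cost) {
  e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE,
             fitted = FALSE)
}

#' Per-feature importance scores from a linear SVM
#'
#' Trains a linear support vector machine on all provided samples and
#' returns one nonnegative importance score per feature, derived from the
#' hyperplane weight vector(s). For a binary problem the score of feature f
#' is \eqn{w_f^2}; for multi-class problems (one-vs-one decomposition into
#' \eqn{|C|(|C|-1)/2} binary machines) it is the sum of \eqn{w_f^2} over the
#' machines — the standard symmetric aggregation for multi-class RFE ranking.
#'
#' @param x Numeric matrix (samples x features) or a `labeled_dataset`.
#' @param y Class labels (ignored when `x` is a `labeled_dataset`).
#' @param cost Soft-margin cost parameter C (default 1, the libsvm default).
#' @param standardize If `TRUE` (default), columns are z-scored on the
#'   provided samples before training. Linear-SVM weights are scale
#'   sensitive, so the scaling convention is explicit. Constant columns map
#'   to all-zero columns and get score 0.
#' @return Named numeric vector of scores, one per column of `x`, all finite
#'   and `>= 0`.
#' @export
svm_weight_scores <- function(x, y = NULL, cost = 1, standardize = TRUE) {
  xy <- as_xy(x, y)
  x <- xy$x
  y <- droplevels(xy$y)
  if (standardize) x <- zscore_apply(x, zscore_fit(x))
  model <- train_linear_svm(x, y, cost)
  W <- pairwise_weights(model)
  scores <- colSums(W^2)
  names(scores) <- colnames(x)
  scores
}

#' Stratified d-fold cross-validated accuracy of a linear SVM
#'
#' Splits the samples into `d` stratified folds (each class dealt
#' round-robin after a seeded shuffle), trains a linear SVM on each training
#' part and counts correct predictions on the held-out part; every sample is
#' tested exactly once. When `standardize` is `TRUE`, z-scoring parameters
#' are estimated on each fold's training part only and applied to its test
#' part, so no test information leaks into the scaling.
#'
#' @inheritParams svm_weight_scores
#' @param d Number of folds (must not exceed the smallest class size).
#' @param seed Integer seed for the fold shuffle.
#' @return Accuracy in `[0, 1]`.
#' @export
svm_cv_accuracy <- function(x, y = NULL, d = 5, cost = 1, seed = 1,
                            standardize = TRUE) {
  xy <- as_xy(x, y)
  x <- xy$x
  y <- droplevels(xy$y)
  folds <- stratified_folds(y, d, seed)
  correct <- 0L
  for (f in seq_len(d)) {
    tr <- folds != f
    xtr <- x[tr, , drop = FALSE]
    xte <- x[!tr, , drop = FALSE]
    if (standardize) {
      zs <- zscore_fit(xtr)
      xtr <- zscore_apply(xtr, zs)
      xte <- zscore_apply(xte, zs)
    }
    model <- train_linear_svm(xtr, droplevels(y[tr]), cost)
    pred <- stats::predict(model, xte)
    correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
  }
  correct / length(y)
}
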