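#' Confusion-matrix metrics
#'
#' Accuracy for any number of classes; sensitivity and specificity with
#' respect to a designated positive class for binary problems.
#'
#' @param truth True class labels.
#' @param predicted Predicted class labels, same length.
#' @param positive_class The class treated as positive for sensitivity
#'   (true-positive rate) and specificity (true-negative rate). Required for
#'   the binary metrics; must be one of the observed classes.
#' @return Named list with `accuracy`, and for two-class data `sensitivity`
#'   and `specificity` (otherwise `NA`).
#' @examples
#' truth <- rep(c("pos", "neg"), c(10, 10))
#' pred <- c(rep("pos", 9), "neg", rep("neg", 8), "pos", "pos")
#' confusion_metrics(truth, pred, positive_class = "pos")
#' @export
confusion_metrics <- function(truth, predicted, positive_class = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) == 0L) stop("labels must be non-empty", call. = FALSE)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted differ in length", call. = FALSE)
  }
  acc <- mean(truth == predicted)
  classes <- sort(unique(truth))
  sens <- spec <- NA_real_
  if (length(classes) == 2L) {
    if (is.null(positive_class)) positive_class <- classes[1L]
    if (!positive_class %in% classes) {
      stop("positive class '", positive_class, "' absent from label set",
           call. = FALSE)
    }
    pos <- truth == positive_class
    sens <- sum(pos & predicted == positive_class) / sum(pos)
    spec <- sum(!pos & predicted != positive_class) / sum(!pos)
  }
  list(accuracy = acc, sensitivity = sens, specificity = spec)
}

#' Repeated stratified cross-validated evaluation of a selector
#'
#' The benchmarking protocol for feature selectors on small-sample data:
#' repeated stratified outer cross-validation with the selector nested
#' inside each training fold. Per repeat, a fresh stratified split is drawn;
#' per fold, the selector runs on the training part only, a final linear
#' SVM is fit on the training part restricted to the selected features, and
#' accuracy (plus sensitivity and specificity for binary problems) is
#' measured on the held-out part. The held-out samples never influence
#' selection, scaling, or training. The field-standard protocol is 5-fold
#' cross-validation repeated 50 times.
#'
#' Outer splits depend only on the root seed and the repeat index — not on
#' the selector — so two selectors evaluated with the same seed see
#' identical folds and can be compared pairwise. Two invocations with an
#' identical configuration produce identical reports.
#'
#' @inheritParams svm_rfe
#' @param outer_folds Outer fold count (default 5); must not exceed the
#'   smallest class size.
#' @param repeats Number of outer repetitions (default 50).
#' @param positive_class Positive class for binary sensitivity/specificity;
#'   default: first class in sorted label order (reported in the protocol).
#' @return An object of class `svm_rfe_cv`: `detail` (one row per repeat and
#'   fold: accuracy, sensitivity, specificity, n_selected), `summary`
#'   (pooled mean and standard deviation per metric across all repeat-fold
#'   cells), `protocol`, and `folds` (per-repeat fold assignments, for
#'   audit).
#' @examples
#' sim <- simulate_hdlss(n_per_class = c(10, 10), m = 25, q = 5, delta = 3)
#' cv <- cross_validate(sim$x, sim$y, method = "svm-rfe-oa", k = 5,
#'                      outer_folds = 5, repeats = 2, seed = 11)
#' cv$summary
#' @export
cross_validate <- function(x, y = NULL,
                           method = c("svm-rfe-oa", "svm-rfe",
                                      "m-svm-rfe-oa"),
                           k = 9, t = 0.05, d = 5, outer_folds = 5,
                           repeats = 50, cost = 1, seed = 1,
                           standardize = TRUE, positive_class = NULL,
                           screen_accuracy = c("cv", "train")) {
  method <- match.arg(method)
  screen_accuracy <- match.arg(screen_accuracy)
  xy <- as_xy(x, y)
  x <- xy$x
  y <- xy$y
  if (outer_folds > min(table(y))) {
    stop("outer_folds exceeds the smallest class size", call. = FALSE)
  }
  binary <- nlevels(y) == 2L
  if (binary && is.null(positive_class)) {
    positive_class <- sort(levels(y))[1L]
  }
  if (!binary && !is.null(positive_class)) {
    stop("sensitivity/specificity require exactly 2 classes", call. = FALSE)
  }

  rows <- vector("list", repeats * outer_folds)
  fold_list <- vector("list", repeats)
  ri <- 0L
  for (r in seq_len(repeats)) {
    folds <- stratified_folds(y, outer_folds, derive_seed(seed, 101, r))
    fold_list[[r]] <- folds
    for (f in seq_len(outer_folds)) {
      tr <- folds != f
      fit <- svm_rfe(x[tr, , drop = FALSE], droplevels(y[tr]),
                     method = method, k = k, t = t, d = d, cost = cost,
                     seed = derive_seed(seed, 202, r, f),
                     standardize = standardize,
                     screen_accuracy = screen_accuracy)
      pred <- predict(fit, x[!tr, , drop = FALSE])
      cm <- confusion_metrics(y[!tr], pred,
                              positive_class = if (binary) positive_class)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(repeat_ = r, fold = f,
                               accuracy = cm$accuracy,
                               sensitivity = cm$sensitivity,
                               specificity = cm$specificity,
                               n_selected = length(fit$selected))
    }
  }
  detail <- do.call(rbind, rows)
  names(detail)[1L] <- "repeat"

  metrics <- c("accuracy", "sensitivity", "specificity", "n_selected")
  summ <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(mm) mean(detail[[mm]]), numeric(1)),
    sd = vapply(metrics, function(mm) stats::sd(detail[[mm]]), numeric(1)),
    row.names = NULL
  )
  if (!binary) summ <- summ[summ$metric %in% c("accuracy", "n_selected"), ]

  structure(list(
    detail = detail,
    summary = summ,
    folds = fold_list,
    protocol = list(method = method, k = k, t = t, d = d, cost = cost,
                    outer_folds = outer_folds, repeats = repeats,
                    seed = seed, standardize = standardize,
                    positive_class = positive_class,
                    screen_accuracy = if (method == "m-svm-rfe-oa")
                      screen_accuracy else NA,
                    sd_convention = "pooled across repeat-fold cells")
  ), class = "svm_rfe_cv")
}

#' @export
print.svm_rfe_cv <- function(x, ...) {
  p <- x$protocol
  cat("Repeated stratified CV evaluation\n")
  cat(sprintf("  selector: %s | %d-fold x %d repeats | k = %s, t = %s, seed = %s\n",
              p$method, p$outer_folds, p$repeats, p$k, p$t, p$seed))
  if (!is.null(p$positive_class)) {
    cat("  positive class:", p$positive_class, "\n")
  }
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' @export
summary.svm_rfe_cv <- function(object, ...) object$summary
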