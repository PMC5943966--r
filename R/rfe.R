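#' Remove the bottom-ranked fraction of a feature ranking
#'
#' One elimination step of recursive feature elimination: given features
#' ranked best-first, drop the bottom `max(1, floor(t * length(ranked)))`.
#' The floor-with-minimum-one rule guarantees every step removes at least
#' one feature, so the elimination loop always terminates; survivors keep
#' their relative rank order.
#'
#' @param ranked Vector of feature identifiers, best-ranked first.
#' @param t Filter factor, the fraction eliminated per iteration
#'   (`0 < t < 1`; the field-standard default is 0.05).
#' @return The surviving features, in unchanged order.
#' @examples
#' length(eliminate_fraction(1:2000, 0.05))  # 1900 survive
#' eliminate_fraction(letters[1:10], 0.05)   # floor(0.5) -> still drops 1
#' @export
eliminate_fraction <- function(ranked, t) {
  if (length(ranked) == 0L) stop("ranked feature list is empty", call. = FALSE)
  if (!is.numeric(t) || length(t) != 1L || t <= 0 || t >= 1) {
    stop("filter factor t must lie strictly between 0 and 1", call. = FALSE)
  }
  drop_n <- max(1L, as.integer(floor(t * length(ranked))))
  ranked[seq_len(length(ranked) - drop_n)]
}

# Screening decision given precomputed Nr values. For each class c with
# members theta_c, let X_c = {samples of c with Nr > 0}. If |X_c| > theta_c/3
# the floor(theta_c/3) largest-Nr members are set aside, otherwise all of
# X_c; so at most one third of each class is ever removed and (for classes
# of size >= 2) no class is emptied. Nr ties break by ascending sample index.
screen_by_nr <- function(nr, y) {
  y <- as.factor(y)
  removed <- integer(0)
  cls <- levels(y)
  removed_by_class <- stats::setNames(vector("list", length(cls)), cls)
  theta <- stats::setNames(as.integer(table(y)[cls]), cls)
  for (cl in cls) {
    members <- which(y == cl)
    xc <- members[nr[members] > 0]
    if (length(xc) > theta[[cl]] / 3) {
      cap <- as.integer(floor(theta[[cl]] / 3))
      xc_ranked <- xc[order(-nr[xc], xc)]
      out <- xc_ranked[seq_len(cap)]
    } else {
      out <- xc
    }
    removed_by_class[[cl]] <- out
    removed <- c(removed, out)
  }
  removed <- sort(removed)
  retained <- setdiff(seq_along(y), removed)
  stopifnot(all(table(y[retained])[cls] >= 1L))
  structure(list(retained = retained, removed = removed,
                 removed_by_class = removed_by_class, class_sizes = theta),
            class = "overlap_screening")
}

#' Screen out heavily overlapping samples
#'
#' Computes the overlap profile on a feature subspace and temporarily sets
#' aside the samples lying in a class-overlap region: per class, the samples
#' with Nr(x) > 0, largest Nr first, capped at one third of the class (so a
#' class is never hollowed out). This is the per-iteration sample filter of
#' the modified overlap-aware selector — screened samples are excluded from
#' SVM training for one iteration only.
#'
#' @inheritParams overlap_profile
#' @return An `overlap_screening` list: `retained` and `removed` sample
#'   indices, `removed_by_class`, `class_sizes`, plus the `profile` used.
#' @examples
#' sim <- simulate_hdlss(n_per_class = c(15, 15), m = 30, q = 5, delta = 6)
#' screen_overlapping_samples(sim$x, sim$y, k = 5)  # separable: none removed
#' @export
screen_overlapping_samples <- function(x, y = NULL, k = 9, features = NULL) {
  if (inherits(x, "labeled_dataset")) {
    y <- x$y
    x <- x$x
  }
  prof <- overlap_profile(x, y, k, features)
  res <- screen_by_nr(prof$nr, y)
  res$profile <- prof
  res
}

#' @export
print.overlap_screening <- function(x, ...) {
  cat("Overlap screening:", length(x$removed), "of",
      sum(x$class_sizes), "samples set aside\n")
  rem <- vapply(x$removed_by_class, length, integer(1))
  print(data.frame(class = names(x$class_sizes), size = x$class_sizes,
                   removed = rem[names(x$class_sizes)], row.names = NULL))
  invisible(x)
}

#' Overlap-aware recursive feature elimination with a linear SVM
#'
#' Fits one of three backward feature-elimination selectors to a labeled
#' sample-by-feature matrix and returns the selected feature subset together
#' with the full per-iteration trace. All three share the same loop: train a
#' linear SVM on the active feature set, rank features by squared hyperplane
#' weight (summed over the one-vs-one machines for multi-class data), drop
#' the bottom fraction `t`, and repeat until no feature is left. They differ
#' in how each iteration's feature subset is scored, and the returned subset
#' is the active set of the best-scoring iteration:
#'
#' \describe{
#'   \item{`"svm-rfe"`}{classic accuracy-driven selection — the score is the
#'     inner `d`-fold cross-validated accuracy alone. Accuracy is quantized
#'     (multiples of 1/n), so ties at the maximum are common; they are
#'     resolved to the latest iteration, i.e. the smallest subset attaining
#'     maximal accuracy is kept, the parsimony convention under which this
#'     baseline is known to select very small gene panels.}
#'   \item{`"svm-rfe-oa"`}{overlap-aware selection — the score is
#'     `T_c_acc - T_c_oa`, cross-validated accuracy minus the average
#'     normalized overlap degree Nr(x) of the training samples on the active
#'     subspace. A subset must both classify well and spatially separate the
#'     classes. The incumbent is replaced only on strict improvement (score
#'     ties go to the earliest, largest subset) and the running best starts
#'     at `c_acc = 0`, `c_oa = Inf`, so the first iteration always becomes
#'     the incumbent.}
#'   \item{`"m-svm-rfe-oa"`}{modified overlap-aware selection — per
#'     iteration, samples in heavy overlap (Nr(x) > 0, at most one third per
#'     class, largest Nr first) are screened out before the SVM is trained,
#'     so the hyperplane and the feature weights are estimated on the
#'     cleaner sample set; `T_c_oa` averages the pre-screening Nr values
#'     over the retained samples. Screening is per-iteration only — samples
#'     return to the pool at the next iteration.}
#' }
#'
#' @param x Numeric matrix (samples x features) or a `labeled_dataset`.
#' @param y Class labels (ignored when `x` is a `labeled_dataset`).
#' @param method Selector, one of `"svm-rfe"`, `"svm-rfe-oa"`,
#'   `"m-svm-rfe-oa"`.
#' @param k Neighbourhood size for the overlap degree (default 9).
#' @param t Filter factor: fraction of the active features eliminated per
#'   iteration (default 0.05); at least one feature is always removed.
#' @param d Inner cross-validation fold count for `T_c_acc` (default 5). It
#'   is clamped to the smallest class size of the samples actually used for
#'   training in an iteration.
#' @param cost Linear-SVM cost parameter C (default 1).
#' @param seed Root seed; all inner-fold shuffles are derived from it, so a
#'   full run is bit-reproducible.
#' @param standardize Z-score features from the current training samples at
#'   each iteration (default `TRUE`). Overlap profiles use the z-scoring of
#'   the full training set.
#' @param screen_accuracy For `"m-svm-rfe-oa"` only: whether `T_c_acc` is
#'   the cross-validated accuracy on the retained samples (`"cv"`, default)
#'   or the training accuracy of the screened-fit SVM (`"train"`).
#' @return An object of class `svm_rfe` with components `selected` (the
#'   chosen features, ranked by descending weight in the winning iteration),
#'   `winning_iteration`, `trace` (data frame: iteration, n_features,
#'   t_c_acc, t_c_oa, score, n_screened), `trace_features` /
#'   `trace_screened` (per-iteration active-set rankings and screened sample
#'   indices), `ranking` (all features, most important first, from the
#'   elimination order), and the fitted final model for [predict.svm_rfe()].
#' @examples
#' sim <- simulate_hdlss(n_per_class = c(15, 15), m = 40, q = 5, delta = 3)
#' fit <- svm_rfe(sim$x, sim$y, method = "svm-rfe-oa", k = 5, seed = 7)
#' fit
#' head(summary(fit)$trace)
#' @seealso [cross_validate()] for nested evaluation,
#'   [write_selection()] for exporting results.
#' @export
svm_rfe <- function(x, y = NULL,
                    method = c("svm-rfe-oa", "svm-rfe", "m-svm-rfe-oa"),
                    k = 9, t = 0.05, d = 5, cost = 1, seed = 1,
                    standardize = TRUE, screen_accuracy = c("cv", "train")) {
  method <- match.arg(method)
  screen_accuracy <- match.arg(screen_accuracy)
  xy <- as_xy(x, y)
  x <- xy$x
  y <- xy$y
  n <- nrow(x)
  m <- ncol(x)
  use_overlap <- method %in% c("svm-rfe-oa", "m-svm-rfe-oa")
  if (use_overlap && k >= n) {
    stop("k must be smaller than the number of samples", call. = FALSE)
  }
  if (!is.numeric(t) || t <= 0 || t >= 1) {
    stop("filter factor t must lie strictly between 0 and 1", call. = FALSE)
  }
  if (cost <= 0) stop("cost must be positive", call. = FALSE)

  # Per-feature z-scoring parameters do not depend on the active subset, so
  # standardizing the full training set once is identical to re-deriving
  # them each iteration; screened fits re-standardize on the retained rows.
  xz <- if (standardize) zscore_apply(x, zscore_fit(x)) else x

  active <- seq_len(m)            # active features, current rank order
  best_score <- -Inf
  best_iter <- NA_integer_
  selected <- integer(0)
  iter <- 0L
  elim_order <- integer(0)        # features in elimination order, first out
  it_iter <- integer(0); it_nf <- integer(0)
  it_acc <- numeric(0); it_oa <- numeric(0); it_score <- numeric(0)
  it_nscreen <- integer(0)
  trace_features <- list()
  trace_screened <- list()

  while (length(active) > 0L) {
    iter <- iter + 1L
    F <- active

    nr <- NULL
    screened <- integer(0)
    rows <- seq_len(n)
    if (use_overlap) {
      prof <- overlap_profile(xz, y, k, features = F)
      nr <- prof$nr
    }
    if (method == "m-svm-rfe-oa") {
      scr <- screen_by_nr(nr, y)
      screened <- scr$removed
      rows <- scr$retained
    }

    xtr <- x[rows, F, drop = FALSE]
    ytr <- droplevels(y[rows])
    if (standardize) {
      zs <- zscore_fit(xtr)
      xtr_z <- zscore_apply(xtr, zs)
    } else {
      xtr_z <- xtr
    }
    model <- train_linear_svm(xtr_z, ytr, cost)
    w2 <- colSums(pairwise_weights(model)^2)

    d_use <- min(d, min(table(ytr)))
    if (method == "m-svm-rfe-oa" && screen_accuracy == "train") {
      pred <- stats::predict(model, xtr_z)
      t_c_acc <- mean(as.character(pred) == as.character(ytr))
    } else {
      t_c_acc <- svm_cv_accuracy(xtr, ytr, d = d_use, cost = cost,
                                 seed = derive_seed(seed, iter),
                                 standardize = standardize)
    }
    t_c_oa <- if (!use_overlap) NA_real_ else if (method == "m-svm-rfe-oa")
      mean(nr[rows]) else mean(nr)
    score <- if (use_overlap) t_c_acc - t_c_oa else t_c_acc

    # rank active features by descending weight, ties to the lower
    # original feature index
    ranked <- F[order(-w2, F)]

    it_iter[iter] <- iter
    it_nf[iter] <- length(F)
    it_acc[iter] <- t_c_acc
    it_oa[iter] <- t_c_oa
    it_score[iter] <- score
    it_nscreen[iter] <- length(screened)
    trace_features[[iter]] <- ranked
    trace_screened[[iter]] <- screened

    improved <- if (use_overlap) score > best_score else score >= best_score
    if (improved) {
      best_score <- score
      best_iter <- iter
      selected <- ranked
    }

    survivors <- eliminate_fraction(ranked, t)
    # record the removed block worst-first so the final rev() yields a
    # best-first ranking within as well as across iterations
    elim_order <- c(elim_order, rev(setdiff(ranked, survivors)))
    active <- survivors
  }

  feature_names <- colnames(x)
  ranking <- rev(elim_order)      # last eliminated = most important
  trace <- data.frame(iteration = it_iter, n_features = it_nf,
                      t_c_acc = it_acc, t_c_oa = it_oa, score = it_score,
                      n_screened = it_nscreen)

  # final classifier on the selected subspace, for predict()
  xs <- x[, selected, drop = FALSE]
  zs_final <- if (standardize) zscore_fit(xs) else NULL
  xs_z <- if (standardize) zscore_apply(xs, zs_final) else xs
  final_model <- train_linear_svm(xs_z, y, cost)
  final_scores <- colSums(pairwise_weights(final_model)^2)
  names(final_scores) <- feature_names[selected]

  structure(list(
    selected = feature_names[selected],
    selected_idx = selected,
    winning_iteration = best_iter,
    trace = trace,
    trace_features = trace_features,
    trace_screened = trace_screened,
    ranking = feature_names[ranking],
    method = method,
    config = list(method = method, k = k, t = t, d = d, cost = cost,
                  seed = seed, standardize = standardize,
                  screen_accuracy = if (method == "m-svm-rfe-oa")
                    screen_accuracy else NA),
    levels = levels(y),
    n = n, m = m,
    final_model = final_model,
    final_scale = zs_final,
    final_scores = final_scores,
    call = match.call()
  ), class = "svm_rfe")
}

# Recompute the winning iteration from a stored trace under the selector's
# own tie rule: first-maximum for the overlap-aware score (strict-improvement
# updates), last-maximum for the accuracy-only baseline (update on >=).
# Exposed internally for audit tests.
selection_from_trace <- function(object) {
  stopifnot(inherits(object, "svm_rfe"))
  win <- if (object$method == "svm-rfe") {
    argmax_last(object$trace$score)
  } else {
    argmax_first(object$trace$score)
  }
  list(winning_iteration = win,
       selected_idx = object$trace_features[[win]])
}

#' @export
print.svm_rfe <- function(x, ...) {
  cat("Overlap-aware SVM-RFE selection\n")
  cat("  selector:      ", x$method, "\n")
  cat("  data:          ", x$n, "samples x", x$m, "features,",
      length(x$levels), "classes\n")
  cat("  iterations:    ", nrow(x$trace), "\n")
  cat("  winning iter.: ", x$winning_iteration,
      sprintf("(T_c_acc = %.4f, T_c_oa = %s, score = %.4f)",
              x$trace$t_c_acc[x$winning_iteration],
              format(x$trace$t_c_oa[x$winning_iteration], digits = 4),
              x$trace$score[x$winning_iteration]), "\n")
  cat("  selected:      ", length(x$selected), "features\n")
  sel <- x$selected
  if (length(sel) > 8) sel <- c(sel[1:8], "...")
  cat("   ", paste(sel, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.svm_rfe <- function(object, ...) {
  structure(list(method = object$method,
                 config = object$config,
                 n = object$n, m = object$m,
                 n_selected = length(object$selected),
                 winning_iteration = object$winning_iteration,
                 trace = object$trace,
                 selected = object$selected),
            class = "summary.svm_rfe")
}

#' @export
print.summary.svm_rfe <- function(x, ...) {
  cat("Selector:", x$method, "|", x$n, "samples,", x$m, "features\n")
  cfg <- x$config
  cat(sprintf("Config: k = %s, t = %s, d = %s, cost = %s, seed = %s\n",
              cfg$k, cfg$t, cfg$d, cfg$cost, cfg$seed))
  cat("Winning iteration", x$winning_iteration, "of", nrow(x$trace),
      "->", x$n_selected, "features\n\nTrace (head):\n")
  print(utils::head(x$trace, 10))
  invisible(x)
}

#' Importance scores of the selected features
#'
#' @param object An `svm_rfe` fit.
#' @param ... Unused.
#' @return Named vector of squared-weight scores of the final linear SVM
#'   refit on the selected subspace, in selection rank order.
#' @export
coef.svm_rfe <- function(object, ...) {
  object$final_scores
}

#' Predict class labels for new samples
#'
#' Applies the final linear SVM (trained on all fitting samples restricted
#' to the selected feature subset, with the fitting samples' z-scoring) to
#' new data.
#'
#' @param object An `svm_rfe` fit.
#' @param newdata Numeric matrix with the same feature columns as the
#'   fitting data (by name, or by position if unnamed).
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.svm_rfe <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  idx <- if (!is.null(colnames(newdata)) &&
             all(object$selected %in% colnames(newdata))) {
    object$selected
  } else {
    object$selected_idx
  }
  xs <- newdata[, idx, drop = FALSE]
  if (!is.null(object$final_scale)) {
    xs <- zscore_apply(xs, object$final_scale)
  }
  stats::predict(object$final_model, xs)
}

#' Plot the selection trace
#'
#' Subset score against the active feature-set size over the elimination
#' path, with the winning iteration marked. For overlap-aware selectors the
#' accuracy and overlap components are overlaid.
#'
#' @param x An `svm_rfe` fit.
#' @param ... Passed to [plot()].
#' @export
plot.svm_rfe <- function(x, ...) {
  tr <- x$trace
  graphics::plot(tr$n_features, tr$score, type = "b", log = "x", pch = 20,
                 xlab = "active features (log scale)",
                 ylab = "subset score",
                 main = paste("Elimination trace:", x$method), ...)
  graphics::abline(v = tr$n_features[x$winning_iteration], lty = 2,
                   col = "grey40")
  if (x$method != "svm-rfe") {
    graphics::lines(tr$n_features, tr$t_c_acc, type = "b", pch = 1,
                    col = "steelblue")
    graphics::lines(tr$n_features, tr$t_c_oa, type = "b", pch = 2,
                    col = "firebrick")
    graphics::legend("bottomright",
                     legend = c("score", "T_c_acc", "T_c_oa"),
                     pch = c(20, 1, 2),
                     col = c("black", "steelblue", "firebrick"),
                     bty = "n")
  }
  invisible(x)
}
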