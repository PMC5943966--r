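test_that("the elimination step follows the floor-with-minimum-one rule", {
  expect_length(eliminate_fraction(seq_len(2000), 0.05), 1900)  # 100 removed
  expect_length(eliminate_fraction(seq_len(10), 0.05), 9)       # min one
  expect_length(eliminate_fraction(seq_len(1), 0.5), 0)         # terminates
  # survivors keep their rank order
  expect_equal(eliminate_fraction(c(7, 3, 9, 1), 0.25), c(7, 3, 9))
  expect_error(eliminate_fraction(integer(0), 0.05), "empty")
  expect_error(eliminate_fraction(1:5, 0), "strictly between")
  expect_error(eliminate_fraction(1:5, 1), "strictly between")
})

test_that("the full elimination schedule matches the arithmetic oracle", {
  for (m0 in c(1, 7, 64, 2000)) {
    expected <- naive_schedule(m0, 0.05)
    active <- seq_len(m0)
    got <- integer(0)
    while (length(active) > 0) {
      got <- c(got, length(active))
      active <- eliminate_fraction(active, 0.05)
    }
    expect_equal(got, expected)
  }
})

test_that("screening caps removals at a third of each class, largest Nr first", {
  # 15 of 30 class members over the threshold -> exactly floor(30/3) = 10
  # removed, and precisely the 10 with the largest Nr
  y <- factor(rep(c("a", "b"), each = 30))
  nr <- c(seq(-1, 1, length.out = 30), rep(-1, 30))
  names_pos <- which(nr > 0 & y == "a")
  res <- svmrfeoa:::screen_by_nr(nr, y)
  expect_length(res$removed_by_class$a, 10)
  expect_equal(sort(res$removed_by_class$a),
               sort(order(nr, decreasing = TRUE)[1:10]))
  expect_length(res$removed_by_class$b, 0)

  # 5 of 30 over the threshold (5 <= 30/3) -> all 5 removed
  nr2 <- rep(-0.5, 60)
  nr2[c(2, 9, 15, 21, 28)] <- 0.4
  res2 <- svmrfeoa:::screen_by_nr(nr2, y)
  expect_equal(res2$removed, c(2, 9, 15, 21, 28))

  # theta = 9 with all 9 over the threshold -> floor(9/3) = 3 removed
  y3 <- factor(rep(c("a", "b"), each = 9))
  nr3 <- c(seq(0.1, 0.9, by = 0.1), rep(-1, 9))
  res3 <- svmrfeoa:::screen_by_nr(nr3, y3)
  expect_equal(res3$removed, c(7, 8, 9))  # the three largest Nr

  # Nr ties break by ascending sample index
  nr4 <- c(rep(0.5, 9), rep(-1, 9))
  res4 <- svmrfeoa:::screen_by_nr(nr4, y3)
  expect_equal(res4$removed, c(1, 2, 3))
})

test_that("screening never exceeds the cap on randomized inputs", {
  set.seed(77)
  for (case in 1:200) {
    n_cls <- sample(2:4, 1)
    sizes <- sample(3:20, n_cls, replace = TRUE)
    y <- factor(rep(seq_len(n_cls), sizes))
    nr <- runif(sum(sizes), -1, 1)
    res <- svmrfeoa:::screen_by_nr(nr, y)
    expect_true(all(nr[res$removed] > 0))
    for (cl in levels(y)) {
      rem <- res$removed_by_class[[cl]]
      theta <- sum(y == cl)
      expect_lte(length(rem), floor(theta / 3))
      # removed are the top-Nr positives of the class
      pos <- which(y == cl & nr > 0)
      keep_pos <- setdiff(pos, rem)
      if (length(rem) && length(keep_pos)) {
        expect_gte(min(nr[rem]), max(nr[keep_pos]))
      }
      expect_gte(sum(y[res$retained] == cl), 1)
    }
  }
})

test_that("separable data is never screened", {
  sim <- separable_blobs(n_per_class = c(12, 12), seed = 13)
  res <- screen_overlapping_samples(sim$x, sim$y, k = 5)
  expect_length(res$removed, 0)
  expect_equal(res$retained, 1:24)
})

test_that("selectors terminate, shrink monotonically and audit cleanly", {
  sim <- simulate_hdlss(n_per_class = c(10, 10), m = 40, q = 5, delta = 2,
                        label_noise = 0.1, seed = 17)
  for (method in c("svm-rfe", "svm-rfe-oa", "m-svm-rfe-oa")) {
    fit <- svm_rfe(sim, method = method, k = 5, d = 4, seed = 17)
    tr <- fit$trace
    expect_lte(nrow(tr), ceiling(log(40) / -log(1 - 0.05)) + 40)
    expect_true(all(diff(tr$n_features) < 0))       # strict shrinkage
    expect_equal(tr$n_features[1], 40)
    # per-iteration active sets are permutations of consistent size
    expect_equal(vapply(fit$trace_features, length, integer(1)),
                 tr$n_features)
    # argmax-with-first-tie over the stored trace reproduces the selection
    audit <- svmrfeoa:::selection_from_trace(fit)
    expect_equal(audit$winning_iteration, fit$winning_iteration)
    expect_equal(fit$selected,
                 colnames(sim$x)[audit$selected_idx])
    # full ranking is a permutation of all features
    expect_setequal(fit$ranking, colnames(sim$x))
  }
})

test_that("the first iteration always becomes the incumbent", {
  # c_acc = 0, c_oa = Inf: any finite first score beats 0 - Inf, so even a
  # useless feature set is selected over nothing
  d <- random_dataset(12, 6, seed = 19)
  fit <- svm_rfe(d$x, d$y, method = "svm-rfe-oa", k = 3, d = 3, seed = 19)
  expect_false(is.na(fit$winning_iteration))
  expect_gte(fit$winning_iteration, 1L)
  scores <- fit$trace$score
  expect_true(all(is.finite(scores)))
  expect_equal(fit$winning_iteration, which.max(scores))
})

test_that("overlap-aware score ties are won by the earliest (largest) subset", {
  expect_equal(svmrfeoa:::argmax_first(c(0.8, 0.9, 0.9, 0.7)), 2L)
  expect_equal(svmrfeoa:::argmax_first(c(0.5, 0.7, 0.7)), 2L)
  expect_equal(svmrfeoa:::argmax_first(c(1, 1, 1)), 1L)
})

test_that("baseline accuracy ties are won by the smallest subset", {
  expect_equal(svmrfeoa:::argmax_last(c(0.8, 0.9, 0.9, 0.7)), 3L)
  expect_equal(svmrfeoa:::argmax_last(c(1, 1, 1)), 3L)
  # separable problem: accuracy plateaus at 1 over many subset sizes and
  # the baseline keeps the smallest of them (the parsimony convention)
  sim <- simulate_hdlss(n_per_class = c(12, 12), m = 50, q = 5, delta = 8,
                        seed = 83)
  fit <- svm_rfe(sim, method = "svm-rfe", d = 4, seed = 83)
  plateau <- which(fit$trace$t_c_acc == max(fit$trace$t_c_acc))
  expect_equal(fit$winning_iteration, max(plateau))
  fit_oa <- svm_rfe(sim, method = "svm-rfe-oa", k = 5, d = 4, seed = 83)
  expect_lte(length(fit$selected), length(fit_oa$selected))
})

test_that("a single-feature input yields a one-iteration trace", {
  set.seed(23)
  y <- rep(c("a", "b"), each = 6)
  x <- matrix(rnorm(12, ifelse(y == "a", -2, 2)), ncol = 1,
              dimnames = list(NULL, "only"))
  fit <- svm_rfe(x, y, method = "svm-rfe", d = 3, seed = 1)
  expect_equal(nrow(fit$trace), 1L)
  expect_equal(fit$selected, "only")
})

test_that("separable blobs drive the overlap-aware selector to a perfect subset", {
  sim <- simulate_hdlss(n_per_class = c(12, 12), m = 55, q = 5, delta = 8,
                        seed = 29)
  fit <- svm_rfe(sim, method = "svm-rfe-oa", k = 5, d = 4, seed = 29)
  win <- fit$trace[fit$winning_iteration, ]
  expect_equal(win$t_c_oa, -1)          # pure neighbourhoods on the subset
  expect_equal(win$t_c_acc, 1.0)
  expect_equal(svm_cv_accuracy(sim$x[, fit$selected, drop = FALSE], sim$y,
                               d = 4, seed = 1), 1.0)
  # the accuracy-only baseline also reaches a perfect subset here
  fit0 <- svm_rfe(sim, method = "svm-rfe", d = 4, seed = 29)
  expect_equal(svm_cv_accuracy(sim$x[, fit0$selected, drop = FALSE], sim$y,
                               d = 4, seed = 1), 1.0)
})

test_that("without screening activity the modified selector equals the plain one", {
  sim <- separable_blobs(n_per_class = c(12, 12), m = 40, q = 5, seed = 31)
  fa <- svm_rfe(sim, method = "svm-rfe-oa", k = 5, d = 4, seed = 7)
  fm <- svm_rfe(sim, method = "m-svm-rfe-oa", k = 5, d = 4, seed = 7)
  expect_true(all(fm$trace$n_screened == 0))
  expect_equal(fa$trace, fm$trace)
  expect_identical(fa$selected, fm$selected)
})

test_that("label-flipped samples are screened out in early iterations", {
  sim <- simulate_hdlss(n_per_class = c(20, 20), m = 50, q = 10, delta = 4,
                        label_noise = 0.1, seed = 37)
  flipped <- which(as.character(sim$y) != as.character(sim$y_clean))
  expect_gt(length(flipped), 0)
  fit <- svm_rfe(sim, method = "m-svm-rfe-oa", k = 9, d = 4, seed = 37)
  early <- unique(unlist(fit$trace_screened[1:5]))
  # a flipped sample sits inside the other class, so its neighbourhood is
  # majority-heterogeneous and it lands in the screened set
  expect_gt(mean(flipped %in% early), 0.5)
  expect_true(all(fit$trace$n_screened <= 2 * floor(20 / 3)))
})

test_that("the modified selector supports the training-accuracy variant", {
  sim <- simulate_hdlss(n_per_class = c(10, 10), m = 20, q = 5, delta = 3,
                        label_noise = 0.1, seed = 41)
  fit <- svm_rfe(sim, method = "m-svm-rfe-oa", k = 5, d = 4, seed = 41,
                 screen_accuracy = "train")
  expect_true(all(fit$trace$t_c_acc >= 0 & fit$trace$t_c_acc <= 1))
  expect_s3_class(fit, "svm_rfe")
})

test_that("invalid selector parameters are rejected", {
  d <- random_dataset(10, 5, seed = 43)
  expect_error(svm_rfe(d$x, d$y, method = "svm-rfe-oa", k = 10, seed = 1),
               "k must be smaller")
  expect_error(svm_rfe(d$x, d$y, t = 1.5, seed = 1), "strictly between")
  expect_error(svm_rfe(d$x, d$y, cost = -1, seed = 1), "positive")
})

test_that("model methods expose the fit coherently", {
  sim <- simulate_hdlss(n_per_class = c(10, 10), m = 24, q = 4, delta = 6,
                        seed = 47)
  fit <- svm_rfe(sim, method = "svm-rfe-oa", k = 5, d = 4, seed = 47)
  expect_output(print(fit), "winning iter")
  expect_output(print(summary(fit)), "Trace")
  co <- coef(fit)
  expect_named(co, fit$selected)
  expect_true(all(co >= 0))
  # in-sample prediction on a separable problem is perfect
  expect_equal(as.character(predict(fit, sim$x)), as.character(sim$y))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
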