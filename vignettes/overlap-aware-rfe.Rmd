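---
title: "Overlap-aware SVM-RFE: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlap-aware SVM-RFE: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svmrfeoa)
```

## The problem

Omics classification data — microarray gene expression above all — live in
the "high dimensions, small samples" regime: tens of samples, thousands of
features, two to five classes. Recursive feature elimination with a linear
support vector machine (SVM-RFE) is a standard way to rank features there:
train a linear SVM, rank features by the magnitude of their hyperplane
weights, drop the worst fraction, repeat until nothing is left. The removal
order is the importance ranking. The harder question is *how many* of the
top-ranked features to keep. The classic answer — keep the subset whose
cross-validated accuracy is maximal — uses the classifier's view only, and
at these sample sizes CV accuracy is a coarse, heavily tied, high-variance
statistic.

This package implements a second, geometric view of subset quality and two
selectors built on it.

## The overlap degree

Let $X = \{x_1,\dots,x_n\}$ be the training samples with class labels
$\mathrm{Label}(x_i) \in C$. On a candidate feature subspace $F$, let
$\mathrm{kNN}(x_i)$ be the $k$ nearest other samples of $x_i$ by Euclidean
distance on $F$, $\mathrm{Difflabel}(x_i)$ the number of those neighbours
with a different label, and
$\mathrm{OR}(x_i) = |\{x : \mathrm{Label}(x) \ne \mathrm{Label}(x_i)\}|/n$
the dataset-wide heterogeneous fraction for $x_i$'s class. The overlap
degree and its normalized form are

$$
r(x_i) = \frac{\mathrm{Difflabel}(x_i)}{k} - \mathrm{OR}(x_i),
\qquad
Nr(x_i) = \frac{r(x_i)}{\mathrm{OR}(x_i)}.
$$

$Nr(x_i) = -1$ iff the neighbourhood is pure; $Nr(x_i) > 0$ means the
neighbourhood is more mixed than chance, i.e. $x_i$ sits in a class-overlap
region; the upper bound is $(1-\mathrm{OR})/\mathrm{OR}$. Averaged over the
samples, $Nr$ measures how separated the classes are on $F$: it tends to
$-1$ for cleanly separated classes and concentrates near $0$ when labels
carry no spatial information (the small positive finite-sample bias,
$n/(2(n-1)) - 1/2$ relative to $\mathrm{OR}$ for balanced binary data, is
negligible at the sample sizes involved). `overlap_profile()` computes all
of these per sample; the neighbourhoods are recomputed on each subspace,
because overlap is a property of the subspace.

## The selectors

`svm_rfe()` runs one elimination loop with three scoring rules
(`method =`):

* **`"svm-rfe"`** — score is the inner $d$-fold CV accuracy $T_{c\_acc}$
  alone.
* **`"svm-rfe-oa"`** — score is $T_{c\_acc} - T_{c\_oa}$, where
  $T_{c\_oa}$ is the average $Nr$ over all training samples on the active
  subspace. The incumbent starts at $c_{acc} = 0$, $c_{oa} = \infty$ and is
  replaced only on strict improvement, so iteration 1 always becomes the
  incumbent and ties go to the earliest (largest) subset.
* **`"m-svm-rfe-oa"`** — as above, but before each SVM fit the samples in
  heavy overlap ($Nr > 0$; per class at most $\lfloor\theta_c/3\rfloor$,
  largest $Nr$ first, $\theta_c$ the class size) are screened out for that
  iteration only. The SVM — and hence the feature weights — is estimated on
  the cleaner retained set $X_t$; $T_{c\_oa}$ averages the pre-screening
  $Nr$ values over $X_t$. Screening targets exactly the samples a
  mislabeled or boundary case produces: points lying inside the other
  class's region.

Feature weights come from the linear SVM's hyperplane: for binary problems
the per-feature score is $w_f^2$; for multi-class one-vs-one models it is
$\sum_{\text{machines}} w_f^2$, the symmetric aggregation standard in
multi-class RFE. The decomposition of the libsvm model into its pairwise
hyperplanes is verified in the test suite against the model's own decision
values.

### Tie-breaking in the accuracy-only baseline

CV accuracy takes values on the grid $\{0, 1/n, \dots, 1\}$, so exact ties
at the maximum are pervasive along an elimination path. The two defensible
conventions differ a lot: first-maximum keeps the largest tied subset,
last-maximum the smallest. This package uses **last-maximum (smallest
subset)** for `"svm-rfe"` — the parsimony convention under which the
accuracy-driven baseline is known to select very small gene panels (single
digits on classic microarray benchmarks), which is also what makes it
brittle: discarding almost-tied larger subsets throws away genuinely
informative, correlated features. The overlap-aware score is continuous, so
ties are a measure-zero event there and the strict-improvement (`>`)
update applies unchanged: first maximum, largest subset.

### Algorithm details that needed pinning

* **Elimination size**: $\max(1, \lfloor t\,|F|\rfloor)$ features are
  removed per iteration (default $t = 0.05$). The floor with minimum one
  guarantees termination in at most
  $\lceil \log m / -\log(1-t) \rceil + m$ iterations.
* **Screening cap rounding**: $\lfloor \theta_c/3 \rfloor$ — "at most a
  third" is an upper bound, and flooring respects it for every class size;
  for $\theta_c \ge 2$ a class can never be emptied.
* **Algorithm ambiguity — accuracy after screening**: for
  `"m-svm-rfe-oa"` the accuracy term is, by default, the inner $d$-fold CV
  accuracy on the retained samples $X_t$ (symmetric with the other
  selectors, and not saturated the way a pure training accuracy would be);
  `screen_accuracy = "train"` switches to the training accuracy of the
  screened fit for users who read the procedure that way.
* **Ties**: distance ties in kNN break by ascending sample index (file
  order); $Nr$ ties during screening break by ascending sample index;
  weight ties during ranking break by ascending original feature index.
  All three make runs bit-reproducible.
* **Standardization**: features are z-scored from the *current training
  samples* — the full training set for profiles and unscreened fits, the
  retained $X_t$ for screened fits, and the inner-CV training part only
  inside `svm_cv_accuracy()` (no leakage into the scaling). Per-feature
  z-parameters do not depend on the active subset, so full-set scaling is
  computed once. Constant columns map to all-zero columns (weight exactly
  0) rather than being dropped, keeping feature indices stable. Linear-SVM
  weights are scale-sensitive, so scaling is an explicit, logged choice
  (`standardize = FALSE` turns it off); input files are never rescaled at
  load time, and whether a public matrix was log-transformed upstream is
  the user's call, not guessed here.
* **Inner folds**: stratified (each class dealt round-robin after a seeded
  shuffle) — at $n \approx 60$ unstratified folds regularly lose a class.
  $d = 5$ by default, matching the outer protocol; inside the elimination
  loop $d$ is clamped to the smallest class size of the samples actually
  used for training, since screening can shrink a class below $d$.
* **Cost**: $C = 1$, the libsvm default; configurable.
* **Seeds**: one root seed; every internal shuffle draws from a seed
  derived by a fixed Lehmer-style chaining of stream indices, so full runs
  (and paired comparisons across selectors) are bit-reproducible.

## The evaluation harness

`cross_validate()` implements the standard benchmarking protocol: repeated
stratified outer cross-validation (default 5-fold, 50 repeats) with the
*entire* selector nested inside each training fold; the final linear SVM is
refit on the training fold restricted to the selected subset and scored on
the held-out fold. Outer splits depend only on the root seed and repeat
index, never on the selector, so comparisons are paired. Reported standard
deviations are pooled across all repeat-fold cells (the per-repeat-averaged
alternative is recomputable from the detail rows, which are always
written). Sensitivity and specificity are reported for binary problems
only, with the positive class defaulting to the first sorted label and
echoed in the protocol header.

## The synthetic generator

`simulate_hdlss()` emulates the benchmark regime used throughout the tests:
$n$ per class in the tens, $m$ in the hundreds to thousands, 2-5 classes.
All features are unit-variance Gaussians; $q$ informative features get
equally spaced class means with spacing `delta` (so the adjacent-class gap
is `delta` standard deviations); `label_noise` reassigns a fixed fraction
of samples to a uniformly random *other* class, which plants exactly the
heavy-overlap samples screening is designed to catch. The Gaussian model is
chosen because its limits are analytic — e.g. the one-feature Bayes
accuracy is $\Phi(\delta/2)$, far-separated blobs force every $Nr = -1$,
and $q = 0$ gives a permutation null — which is what makes the test suite's
expected values computable. It deliberately does not model microarray
realities (heavy tails, feature correlation, batch effects, intensity-
dependent variance), so passing tests demonstrate algorithmic correctness
and qualitative behaviour, not clinical performance.

Default problem sizes in the shipped tests were chosen to exercise the
documented regime while keeping a full suite run in the tens of minutes on
one core: oracle checks at $n \le 60$, $m \le 30$; recovery at
$n = 60$, $m = 500$, $q = 10$, $\delta = 2$ over 20 seeds; the noisy
selector comparison at $n = 80$, $m = 300$, $\rho = 0.15$ over 20 paired
seeds of 5-fold outer CV.

## Known limitations

* Brute-force exact kNN and dense distance matrices: right for $n$ up to a
  few hundred, wrong tool beyond that.
* Linear kernels only; no class weighting, no probability outputs.
* Sensitivity/specificity are binary-only; multi-class problems report
  accuracy and panel size.
* The accuracy-overlap score weighs its two terms 1:1; no weighting knob is
  exposed because none is defined in the underlying procedure.
* Screening assumes every class can spare a third of its members; with
  classes of size 2-3 it degenerates gracefully (no removal) but the
  overlap estimates themselves are then very coarse.
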