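# svmrfeoa

Overlap-aware SVM recursive feature elimination for high-dimensional,
small-sample biological data.

## What it is for

Microarray and other omics classification problems typically have tens of
samples and thousands of features. SVM-RFE ranks features by repeatedly
training a linear SVM and discarding the features with the smallest
hyperplane weights; the open question is how many top-ranked features to
keep. The classic rule — keep the subset with maximal cross-validated
accuracy — sees the data only through the classifier, and at these sample
sizes CV accuracy is coarse and heavily tied.

This package adds a geometric criterion. For each training sample $x$ with
$k$ nearest neighbours on the candidate subspace, with
$\mathrm{Difflabel}(x)$ heterogeneous neighbours and class-wise baseline
heterogeneous fraction $\mathrm{OR}(x)$, the normalized overlap degree is

$$r(x) = \frac{\mathrm{Difflabel}(x)}{k} - \mathrm{OR}(x), \qquad
Nr(x) = \frac{r(x)}{\mathrm{OR}(x)} .$$

$Nr(x) = -1$ means a pure same-class neighbourhood; $Nr(x) > 0$ means the
sample lies in a class-overlap region. The average $Nr$ over the training
set measures how separated the classes are on the subspace. Three selectors
share one elimination loop (`t = 5%` of features dropped per iteration,
linear SVM weights, one-vs-one $\sum w_f^2$ aggregation for multi-class):

| selector | subset score per iteration |
|---|---|
| `svm-rfe` | inner $d$-fold CV accuracy $T_{c\_acc}$ |
| `svm-rfe-oa` | $T_{c\_acc} - T_{c\_oa}$, where $T_{c\_oa}$ = average $Nr$ |
| `m-svm-rfe-oa` | as `svm-rfe-oa`, but samples with $Nr > 0$ (at most a third per class, largest $Nr$ first) are screened out of each iteration's SVM fit, stabilising the feature weights against mislabeled and boundary samples |

Also included: a per-sample overlap profiler, a repeated stratified
cross-validation harness (accuracy, sensitivity, specificity, panel size;
nested selection, paired splits across selectors), a synthetic
high-dimension/small-sample generator with planted informative features and
label noise, and a command-line interface.

## Worked example

```r
library(svmrfeoa)

# 50 samples, 200 features, 8 informative (2 sd class gap), 10% label noise
sim <- simulate_hdlss(n_per_class = c(25, 25), m = 200, q = 8, delta = 2,
                      label_noise = 0.1, seed = 42)

overlap_profile(sim$x, sim$y, k = 9)
#> Overlap profile: 50 samples, k = 9
#> average Nr(x): -0.3348
#> samples with Nr(x) > 0: 10

fit <- svm_rfe(sim, method = "m-svm-rfe-oa", k = 9, seed = 7)
fit
#> Overlap-aware SVM-RFE selection
#>   selector:       m-svm-rfe-oa
#>   data:           50 samples x 200 features, 2 classes
#>   iterations:     75
#>   winning iter.:  64 (T_c_acc = 1.0000, T_c_oa = -0.8101, score = 1.8101)
#>   selected:       12 features
#>     f183, f86, f83, f177, f51, f128, f32, f152, ...
mean(sim$informative %in% fit$selected)
#> [1] 0.875
```

The profile says the raw feature space is mildly overlapping (average
$Nr = -0.33$; the 10 samples with $Nr > 0$ are mostly the label-flipped
ones). The selector settles on a 12-feature panel whose subspace is nearly
separated ($T_{c\_oa} = -0.81$) and recovers 7 of the 8 planted markers.
Honest performance comes from the nested harness, where selection reruns
inside every training fold:

```r
cross_validate(sim, method = "m-svm-rfe-oa", k = 9, outer_folds = 5,
               repeats = 2, seed = 7)
#> Repeated stratified CV evaluation
#>   selector: m-svm-rfe-oa | 5-fold x 2 repeats | k = 9, t = 0.05, seed = 7
#>   positive class: c1
#>   accuracy     0.7310 +/- 0.1226
#>   sensitivity  0.7133 +/- 0.1635
#>   specificity  0.7600 +/- 0.2633
#>   n_selected   8.1000 +/- 5.4252
```

With 10% of the labels flipped the achievable accuracy is capped near 0.9;
the in-sample score of 1.0 above is exactly the optimism the outer CV
corrects.

The same runs from a shell:

```sh
exec/svmrfeoa simulate --n 25,25 --m 200 --q 8 --delta 2 --noise 0.1 \
    --seed 42 --out data.tsv
exec/svmrfeoa select --data data.tsv --selector m-svm-rfe-oa --k 9 \
    --seed 7 --out panel.csv
exec/svmrfeoa evaluate --data data.tsv --selector m-svm-rfe-oa --k 9 \
    --outer-folds 5 --repeats 2 --seed 7 --out report.csv
```

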