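---
title: "Optimal training/test splits for high-dimensional classifiers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal training/test splits for high-dimensional classifiers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optsplit)
```

## The design question

In a split-sample study, `n` cases are divided into a training set of size
`t` and a test set of size `n - t`.  The classifier taken forward is the
one developed on the full dataset; the split exists to estimate that
classifier's accuracy.  `optsplit` chooses `t` to minimize the mean
squared error of the hold-out estimate with respect to the full-data
classifier's true accuracy, decomposed into three non-negative parts:

* **A (accuracy variance).**  Different random training sets of size `t`
  yield classifiers with different true accuracies; `A(t)` is the sample
  variance of those accuracies.
* **V (binomial variance).**  Given a classifier with true accuracy `acc`,
  the proportion correct on `n - t` independent test cases has variance
  `acc (1 - acc) / (n - t)`.
* **B (squared bias).**  `(acc(t) - acc(n))^2`, the systematic cost of
  estimating the accuracy of a classifier that saw only `t` of the `n`
  cases.

The decomposition holds up to a constant of proportionality; the package
fixes that constant at 1 because only comparisons across `t` matter for
choosing a split.  `mse = A + V + B` is enforced exactly (elementwise
identity, not within tolerance) on every decomposition object the package
builds.

Typical behaviour, visible in any `run_scenario()` output: `B` dominates
at small `t` and decays as the classifier approaches its achievable
accuracy; `V` grows as the test set shrinks and dominates near `t = n`
unless accuracy is essentially 1; `A` is usually the smallest term.

## The population model and its generator

`simulation_scenario()` describes a two-class population of log-expression
profiles: a `p`-dimensional multivariate normal with common covariance and
a mean shift of `effect * sigma` (the *standardized fold change*) in the
first `m` genes.  `simulate_dataset()` draws fixed class counts
(`round(prevalence * n)` and the complement) rather than Bernoulli labels,
so that small-`n` scenarios cannot produce a degenerate class; informative
genes sit at known indices and are recorded in the dataset's `truth` field
so that tests can score gene selection.

Covariance options: independent genes (`"identity"`, the default used for
the scenario grids), a supplied matrix, diagonal shrinkage
`rho * Diag(S) + (1 - rho) * S` of an empirical covariance
(`cov_shrunken()`), and an equicorrelated block among the informative
genes (`cov_block()`), since correlation among the differentially
expressed genes is one of the quantities the MSE components respond to.
Construction validates symmetry and positive semi-definiteness.

What the generator emulates: the dimensionality (`p` in the thousands
against `n` in the tens to hundreds), sparse-to-diffuse signal, class
imbalance in the 1/3-2/3 range, and gene-gene correlation through the
block or shrunken specifications.  What it does not emulate: non-normal
within-class structure (batch effects, latent subgroups, label noise),
heavy-tailed measurement error, and normalization artifacts.  Passing
tests therefore demonstrate correctness of the machinery and calibration
under the stated model, not robustness to the intra-class heterogeneity
that real tumor datasets can show; on such data the nonparametric engine
is the appropriate tool precisely because it inherits whatever structure
the dataset has.

## The compound covariate predictor

The reference classifier is deliberately simple and linear.  Genes are
selected by pooled-variance two-sample t-tests at significance cutoff
`alpha` (two-sided p-value `<= alpha`; the boundary is included; genes
with zero pooled variance are never selectable).  The compound covariate
is `c(x) = sum_j t_j x_j` over selected genes, weighted by the t
statistics themselves, and the cutpoint `k` is the midpoint of the two
training-class means of `c` — not prevalence-shifted, matching the
classical form of the predictor.  A sample scoring exactly `k` goes to the
high side; an empty selection degenerates to a majority-class rule with
ties toward the first factor level.  These conventions are arbitrary but
documented and tested.

Because `c(x)` is a linear rule, its true accuracy under a known scenario
is available in closed form from two normal tail probabilities of
`(w'mu - k) / sqrt(w' Sigma w)`.  This exact accuracy is what the
parametric engine uses for `A` and `B`; a Monte Carlo cross-check against
fresh draws from the generating model is part of the test suite.

### Choosing the selection cutoff

The optimal `alpha` depends strongly on the training-set size: a cutoff
tuned for 200 cases selects nothing at 10.  `optimal_alpha()` maximizes
expected accuracy over the default grid
`{1e-6, 1e-5, 1e-4, 1e-3, 0.005, 0.01, 0.05, 0.1}` in one of two modes:

* **parametric** — Monte Carlo over simulated training sets of the target
  size, scoring each candidate by the exact model accuracy (50 draws by
  default; the simulated statistics are shared across candidates so the
  cost is one simulation per draw);
* **data** — stratified 5-fold cross-validation on a supplied dataset,
  with class prevalence implicitly estimated from the data rather than
  assumed known.

Ties are broken toward the smaller `alpha` (the sparser model); under an
equal-prevalence null every linear rule has exact accuracy 1/2, so the
tie rule is what makes the null case deterministic.

The nonparametric engine's plug-in CCP (`ccp_classifier()` with
`alpha = NULL`) tunes the cutoff once per training-set *size*, averaging
the cross-validated accuracy profile over three stratified subsets of that
size before committing (a single subset proved a noisy basis for the
choice), and caches the winner for all subsequent splits of the same size.

## The parametric engine

`run_scenario()` follows the simulation pipeline: simulate a dataset,
draw `R` stratified training subsets per grid point (default grid
`10, 20, ..., n - 10`), fit a CCP on each at the per-size optimal cutoff,
and record exact true accuracies (giving `A` and the mean accuracy at `t`)
along with hold-out accuracies on the complementary cases (whose
unbiasedness against the exact accuracies is itself a test).  `V` comes
from the binomial formula at the mean accuracy, and `B` compares the mean
accuracy at `t` with a full-data reference.

Two reference conventions are available.  The default averages the exact
accuracies of full-data classifiers over 50 independent replicate
datasets, which stabilizes scenario-level summaries against the luck of a
single draw.  `full_data_reference = "dataset"` instead conditions on the
study dataset itself — the right comparator when the parametric engine is
run side by side with the nonparametric one on a shared dataset, because
the nonparametric algorithm only ever sees that one dataset.

Defaults worth knowing: `R = 200` subsets per grid point (the reference
procedure uses 1,000; 200 keeps a 19-point grid at `p = 5000` to a few
minutes while the Monte Carlo error of the per-`t` means stays well below
the plateau tolerance), `p = 5000` for scenario grids (desk-scale while
preserving `p >> n`), and stratified subset draws so that even `t = 10`
contains both classes.

## The nonparametric engine

`recommend_split()` estimates the same decomposition for a *specific*
dataset and classifier, with no distributional assumptions:

1. **Learning curve.**  For each `t`, split the dataset at random
   `n_splits` times (stratified), train on one side, measure error on the
   other, and average.  The mean-error curve `w(t)` is smoothed by a
   weighted spline with case weights `1/t` — small-`t` means are based on
   noisier classifiers — and the fit is evaluated on the grid and at
   `t = n`.  If the fitted curve increases anywhere by more than `1e-6`
   between consecutive grid points, the fit falls back to weighted
   isotonic regression (pool-adjacent-violators) in the non-increasing
   direction: error is not allowed to grow with training data, and in
   practice the spline wiggles exactly when the error has stopped
   decreasing relative to the noise level.  The `1e-6` trigger tolerates
   floating-point wiggle only.
2. **Bias.**  `B(t) = (fitted(t) - fitted(n))^2`, from fitted values only,
   so `B(n) = 0` by construction.  Evaluation at `t = n` is an
   extrapolation: the spline extrapolates linearly from its last segment
   (the natural-spline boundary), the isotonic fit extends flat.
3. **Variance.**  For each `t` and each of `n_boot` replicates: a fresh
   stratified split, then resampling with replacement *within* the
   training part and within the test part — splitting before resampling
   keeps the parts disjoint — train, evaluate, and take the sample
   variance of the replicate accuracies.  This estimates the `A + V`
   composite; the package never pretends to separate the two, and the
   decomposition object carries a `"composite"` marker (the composite is
   stored in the `A` slot with `V = 0`, keeping `mse = A + V + B` exact).
   A resample that loses a class is redrawn up to 20 times, then errors.
4. `mse(t)` is the sum; the recommendation reports the RMSE-minimizing
   `t`, the plateau, the excess error of the 1/2 and 2/3 rules, and the
   full-data accuracy `1 - fitted(n)`.

At least 1,000 splits and 1,000 bootstrap replicates are recommended for
de-noised curves; smaller values are accepted with a message, and the
package's own tests run at 30-200 for speed.

Spline degrees of freedom are chosen by generalized cross-validation,
capped at `min(6, #grid points - 2)` — the reference procedure adjusted
them visually per dataset, which is not reproducible in software; the cap
prevents a short noisy grid from being interpolated.  `smoothing_df`
overrides the automation.

## Reading a recommendation

`summarize_mse()` breaks argmin ties toward the smaller `t` (the larger
test set), reports the plateau of training sizes whose RMSE is within
`plateau_tol` of the minimum (default 0.001 — an excess error comparable
to adding a handful of binomial test samples, i.e. practically nothing),
and evaluates the two rules of thumb at the nearest grid points to
`round(n/2)` and `round(2n/3)`.  When the plateau reaches the top of the
grid the formatted scenario-grid cell carries a `+`, e.g. `"70+(>99%)"`:
anything from 70 up is practically equivalent.

When the two engines are compared on one shared dataset, agreement should
be judged plateau-aware: on a flat MSE curve the argmin is located by
noise, while the plateau is the stable object.  Such comparisons are only
meaningful on scenarios with an identifiable optimum in the first place —
when the classes are so widely separated that the full-data accuracy is
essentially 1, the MSE curve is flat at the noise floor and *any* split is
near-optimal, so two engines may "disagree" about the argmin of a curve
with no structure.  Concentrated single-gene signals are the opposite
degenerate case for a *shared-dataset* comparison: one dataset is then an
unrepresentative draw of its population, and the dataset-conditional curve
legitimately differs from the population one.  The package's agreement
tests therefore use diffuse multi-gene signatures with full-data
accuracies in the range real microarray applications show (roughly
0.85-0.97).

## Degenerate inputs and edge rules

* Fewer than 4 grid points cannot be smoothed (error).
* Learning-curve fits are clamped to `[0, 1]` after smoothing.
* Zero-variance genes get `t = 0` and are excluded from selection.
* An empty gene selection yields the majority-class fallback (ties toward
  class 1); its exact accuracy is the fallback class's prevalence.
* A rule whose compound covariate has zero variance under the scenario
  (`w' Sigma w = 0`) raises an error rather than returning 0.5.
* Stratified splits require at least 2 samples per class on each side
  relevant to fitting; scenario construction rejects class sizes below 2.

## Reproducibility

Every public entry point takes a seed; pipelines derive per-component
sub-seeds from a single master seed, so a `run_scenario()` or
`recommend_split()` call — and a CLI run, whose JSON report contains no
timestamps — is bit-reproducible given its seed.  The test suite asserts
this, and asserts that different seeds actually change the draws.

## Known limitations

* The exact-accuracy shortcut exists only for linear rules under the
  normal model; other plug-in classifiers are supported solely through
  the nonparametric engine.
* The bootstrap variance composite inherits the usual resampling
  distortion: resampled training sets contain duplicated samples, which
  inflates the variance estimate somewhat, most visibly at small `t`.
* Severe prevalence imbalance (e.g. 90/10), cost-sensitive objectives,
  and PPV/NPV/AUC-based split criteria are out of scope.
* The parametric learning-curve family `e = a + b / t^alpha` is
  deliberately not offered for bias estimation; the smoothing-spline /
  isotonic route needs no asymptote and fits observed curves better in
  this setting.

## Problem sizes used in the shipped tests

Unit tests run at `p` of 40-500 and `n` of 40-100 with 5-60 resampling
replicates; the end-to-end checks use the scenario grid's `p = 5000` with
100-200 replicate datasets, `R = 200` subsets per grid point for the
weak-signal optimal-split scenario, and `n_splits = n_boot = 200` with
`p = 1000`, `n = 200` for the engine-agreement comparisons.  These sizes
were chosen so the full suite completes in minutes on a single core while
keeping Monte Carlo error well inside each assertion's tolerance.
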