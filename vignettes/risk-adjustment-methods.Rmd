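---
title: "Methods: embedding-based risk adjustment and its actuarial evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: embedding-based risk adjustment and its actuarial evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(franklinra)
```

This vignette is the package's own account of its models and the choices
behind them: what is computed, under which assumptions, which knobs
matter, and what the synthetic experiments do and do not demonstrate.

## The two risk models

**HCC-style baseline.** The baseline scorer is structurally faithful to
hierarchical condition category risk adjustment: a partial map from
diagnosis codes into disease categories, a directed severity hierarchy in
which a present dominant category suppresses its subordinate categories
(transitively — only the most dominant category of each chain survives), a
nonnegative weight per category, demographic (age band × sex) cell
weights, optional category-pair interaction weights, and a base cost in
dollars per unit score. Codes outside the map are silently ignored, which
is the point: the baseline cannot see them. The package does not ship any
proprietary category tables; tests use a small hand-written map, and the
demo pipeline derives a map from the generator's ground truth (below).

**Embedding-cluster model.** The alternative scores complete diagnostic
profiles in four stages.

1. *Co-occurrence.* Each beneficiary's full-year diagnosis set is an
   unordered profile; every unordered pair of distinct in-vocabulary codes
   in a profile increments a symmetric count matrix. There is no temporal
   windowing because the data model has no time axis. Codes must appear in
   at least `min_count = 5` profiles to enter the vocabulary — rarer codes
   produce degenerate embeddings; the floor is configurable.
2. *Embeddings.* The count matrix is transformed to positive pointwise
   mutual information (PPMI), `max(0, log(c_ij S / (r_i r_j)))`, and
   treated as a similarity kernel. Embeddings are the rank-`d` truncated
   eigendecomposition restricted to *positive* eigenvalues, with rows
   `V_d diag(lambda^alpha)`, `alpha = 0.5`. Keeping only the positive
   (positive-semidefinite) part matters: with `alpha = 0.5` the embedding
   Gram matrix reconstructs the PSD part of the PPMI kernel, so cosine
   similarity between two codes directly reflects their co-occurrence
   strength. A plain SVD of the symmetric PPMI would retain
   negative-eigenvalue directions and can place two codes that co-occur
   exclusively with each other at right angles — correct for second-order
   ("shared neighbors") similarity, wrong for the first-order similarity
   the cluster features need. The factorization is an exact LAPACK
   decomposition, hence deterministic; eigenvector signs are normalized so
   each dimension's largest-magnitude loading is positive, making the
   whole embedding matrix bit-reproducible. Default `d = 50`, clipped with
   a warning when the vocabulary (or the kernel's positive rank) is
   smaller.
3. *Clusters.* Spherical k-means — ordinary k-means on length-normalized
   embeddings — groups the codes into `k = 250` clusters (default), with
   10 restarts and the best inertia kept, seeded and reproducible.
   Normalizing first makes the clustering geometry agree with the cosine
   similarity used downstream. `k` is clipped to the number of distinct
   embedding directions; the degenerate `k = vocabulary` case is
   constructed directly (singleton clusters, zero inertia) because
   `stats::kmeans` refuses as many centers as points.
4. *Features and regression.* Feature `j` of a beneficiary is the maximum
   cosine similarity between any of their in-vocabulary code embeddings
   and cluster center `j`; a profile with no in-vocabulary codes gets the
   zero vector, and out-of-vocabulary codes are ignored. Features are
   monotone (adding a code can only raise them) and lie in [−1, 1]. The
   regressor is gradient-boosted trees on `log(cost + c)` with inputs
   (age, male indicator, the `k` features); defaults are 500 trees, depth
   6, learning rate 0.05, 80% row subsampling, early stopping after 20
   stale validation rounds, single-threaded with a fixed seed so the
   training path is reproducible. These are conventional tabular-boosting
   settings, not tuned to any particular cohort, and all overridable.

## From log predictions to payments

Log-scale output is converted to dollars as `exp(pred) − c`, floored at a
$1 payment floor, then multiplied by decile calibration factors: the
calibration set is ranked by predicted cost into ten equal-count deciles
(ties broken stably by input order) and each decile's factor is
mean observed / mean predicted. On the calibration set this makes every
decile's predictive ratio exactly 1 and conserves total dollars; it also
absorbs the retransformation bias that exponentiating log-scale
predictions would otherwise introduce, which is why no separate smearing
estimator is used. The log offset is `c = 1` USD so zero-cost
beneficiaries have a finite target; both `c` and the floor are arguments.

Two evaluation conventions follow the models' native scales. The boosted
model's log-scale fit (R² of log cost) is scored on its log output
directly; its cost-scale metrics use the calibrated dollar predictions.
The baseline predicts dollars, so its log-scale fit uses an affine
recalibration `log(cost + c) ~ log(predicted + c)` fitted by OLS on the
training split and applied out of sample — monotone, rank-preserving, and
two-parameter, so it cannot manufacture skill the score does not have.

## Measuring accuracy and actuarial risk

The fit metrics are R² of log cost, R² of cost, MAE in dollars, Spearman
rho (average-rank ties), and the two-sample Kolmogorov–Smirnov
sup-distance between the distributions of predicted and observed
`log(cost + c)`. Extreme-cost classification takes the `q = 0.20` tails of
the *actual* cost distribution as positives and the same-size tails of the
predicted distribution as predicted positives; with equal tail counts,
sensitivity and precision coincide by construction. Substantial
prediction errors are differences in within-cohort percentile rank
(average-rank ties, 0–100 scale, computed with a single division so exact
boundary cases like a 20.0-point gap are classified consistently);
frequencies are reported at ≥ 20 and ≥ 40 points in both directions.
Within-decile dispersion reports the predictive ratio, the IQR and the
90th-minus-10th percentile range of observed cost per predicted-risk
decile, with percentile-bootstrap CIs. Model comparisons use a paired
t-test over 100 downsampled samples of 1,000 beneficiaries (with
replacement by default, since small synthetic cohorts cannot supply 100
disjoint samples); identical models yield a degenerate all-zero difference
vector, reported as p = 1.

**Dispersion decomposition.** For log-normal costs with log-scale SD
sigma, plan-level predictive-ratio variability decomposes into a
structural factor `exp(sigma^2/2)` — the mean-to-median cost ratio, an
actuarial floor no risk model can shrink — and a residual factor
`exp((1 − R2_log) sigma^2) − 1` that vanishes only for a perfect log-scale
model. The package validates the decomposition by simulation
(`pr_variance_simulation()`): log costs are drawn `N(0, sigma^2)`, and a
model with a given R² of log cost is represented as the *true log cost
plus independent Gaussian noise* with variance `(1 − R2) sigma^2`,
payments being the mean-calibrated exponentiated predictions. Under this
noisy-measurement construction a delta-method calculation gives
`n Var(PR) = exp(sigma^2) (exp((1 − R2) sigma^2) − 1)` — the squared
structural factor times the residual factor — so the *ratio* of PR
variances between two models equals the ratio of their residual factors,
independent of composition and plan size. That ratio is what the tests
check (15% tolerance at sigma = 1.2, plans of 1,000, a few thousand
plans). The alternative construction, a predictor equal to the conditional
mean of cost given a signal, does not have this property; the
noisy-measurement form is the one under which the decomposition is exact,
and it is adopted as the package's simulation design. PR variance also
scales as 1/plan size, which is tested directly.

## The selection simulator

Enrollment probability is
`plogis(qlogis(baseline) + tau (rank_predicted − rank_actual))`, with
percentile ranks normalized to [0, 1] as `(rank − 0.5)/n` so a decile's
representative member sits at the decile midpoint (0.05, …, 0.95). This
normalization is the contract: with a 50% baseline it puts the
bottom-actual/top-predicted-decile enrollment probability at 52% for
τ = 0.1 and 61% for τ = 0.5 to the nearest percent. Each simulated sample
draws N beneficiaries without replacement, enrolls them independently,
and records mean(payment − actual cost) over enrollees; payments must be
PR-calibrated so that τ = 0 is overpayment-neutral. All payment models in
a comparison see identical sampled populations and identical enrollment
uniforms (common random numbers), so per-sample differences are purely
model-driven. Overpayment is signed positive when the payer pays more
than enrollees cost. Desk defaults are 500 samples of plans of 5,000,
configurable upward; `overpayment_curve()` sweeps a τ grid with paired
seeds and reports an R²-against-τ linearity diagnostic.

## The synthetic claims generator

The generator emulates the statistical structure risk adjustment sees in
elderly fee-for-service claims, not any real code ontology:

* K latent conditions with prevalences defaulting to an even spread from
  0.25 down to 0.04 (a mix of common and rarer chronic conditions), each
  owning a block of ICD-10-like codes (letter + two digits + optional
  subcode, so code-format handling is exercised without licensing a real
  code list);
* a present condition emits each owned code independently with
  probability 0.7, plus Poisson(1) uniformly random noise codes per
  beneficiary, so same-condition codes co-occur in blocks;
* annual cost `exp(intercept + age and sex effects + sum of condition
  effects + N(0, sigma_eps^2))`, rounded to whole cents; the default
  intercept `log(2000)` and residual SD 1.0 give a total log-cost SD near
  1.2 and put roughly a fifth of beneficiaries below ~$500 and a fifth
  above ~$7,000 — the right-skewed shape of elderly medical spending;
* condition effects spanning 1.0 down to −0.4 on the log scale, so some
  conditions *lower* expected cost — a boosted model can exploit such
  codes, a nonnegative-weight category model cannot;
* an undercoded stratum (5% by default) whose latent conditions still
  drive cost but whose diagnosis sets are emptied, emulating
  beneficiaries with few or no mapped codes; and an optional zero-cost
  fraction to exercise the log-offset policy.

Ground truth (condition indicators, the code-to-condition map, the true
expected log cost) is returned alongside the cohort, so recovery tests
have an oracle. Identical seeds give byte-identical cohorts.

What passing tests on these cohorts shows: that the pipeline recovers
planted co-occurrence structure, that full-profile scoring beats a
partial-coverage category baseline when cost-relevant codes fall outside
the category map, and that every metric and simulator behaves per its
contract. What it does not show: performance on real claims, where code
assignment is noisier than a block-emission process, costs are not
exactly log-normal, coding intensity varies systematically (upcoding),
and mortality truncates spending. Multi-year longitudinal structure,
utilization events and fairness interventions are out of scope.

## The demo baseline's category map

The end-to-end comparison needs an HCC-style map for synthetic codes.
`demo_category_map()` builds one from ground truth covering a chosen
subset of conditions (default: half): one category per covered condition
mapped from that condition's codes, with weights fitted by least squares
of relative cost (cost over base cost, the training-split mean cost) on
category indicators plus age-band × sex cells, negatives clipped to zero.
This mirrors how category weights are actually calibrated (linear
regression, nonnegative weights) while making the coverage handicap —
the experimental variable — explicit and controllable.

## Scale choices and determinism

Test and demo problem sizes are chosen so the full suite and the
acceptance script each run in minutes on a single core: the end-to-end
comparison uses 20,000 beneficiaries with 10 conditions (4,000 test
rows), the dispersion Monte Carlo a few thousand plans of 1,000, the
structure-recovery check 6,000 beneficiaries, and the fuzz suite 1,000
brute-force trials at sizes ≤ 12. Every stochastic stage (generation,
splitting, clustering restarts, boosting subsampling, bootstraps,
selection sampling) takes an explicit seed, derived from one master seed
in the pipeline, and the package restores the caller's RNG state after
every seeded operation. Identical configuration and seed reproduce the
demo report byte for byte.

## Known limitations

* The embedding objective is fixed (PPMI + positive-part
  eigendecomposition); a skip-gram-style alternative could sit behind the
  same contract but is not implemented.
* The eigendecomposition is dense, which is comfortable to a few thousand
  vocabulary codes and would need an iterative solver beyond that.
* Decile calibration transfers imperfectly between splits: factors fitted
  on a small validation split are noisy, which is visible at desk scale.
* The baseline's demographic cells are fitted jointly with category
  weights by unpenalized least squares; with very small training splits a
  sparse cell can get a clipped, uninformative weight.
* The selection simulator isolates enrollment selection: no plan
  cost-control behavior, benefit design, churn, or national dollar
  extrapolations.
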