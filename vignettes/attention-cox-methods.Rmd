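---
title: "Sequential-attention Cox survival models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential-attention Cox survival models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tabcox)
```

## The model

`tabcox` fits survival models of the proportional-hazards form

$$\lambda(t \mid x) = \lambda_0(t)\, e^{h_\theta(x)},$$

where the scalar log-risk $h_\theta(x)$ is produced by one of three
encoders sharing identical loss machinery: a log-linear predictor
($h = x^\top\beta$, the classical Cox model), a one-hidden-layer
perceptron, or a sequential-attention tabular encoder (TabNet-style).
The attention encoder is the package's focus: at each of $N_{steps}$
decision steps an *attentive transformer* produces a mask
$M^{(i)}[b,\cdot]$ on the feature simplex via

$$M^{(i)} = \mathrm{sparsemax}\left(P^{(i-1)} \odot (a^{(i-1)} W + c)\right),
\qquad P^{(i)} = P^{(i-1)} \odot (\gamma - M^{(i)}),$$

so features consumed at earlier steps are down-weighted later (excluded
outright at $\gamma = 1$). The masked covariates $M^{(i)} \odot x$ pass
through a *feature transformer* — two shared plus two step-specific gated
linear (GLU) blocks with residual scaling $1/\sqrt 2$ — whose output
splits into a decision part (rectified and summed across steps into a
linear log-risk head) and the next attention context $a^{(i)}$.

Training minimizes the total objective

$$L(\theta) = -\sum_{i:E_i=1}\Big[h_\theta(x_i) -
\log \sum_{j \in R(t_i)} e^{h_\theta(x_j)}\Big]
+ \lambda_{sparse}\, \frac{1}{N_{steps} B}
\sum_{s=1}^{N_{steps}} \sum_{b=1}^{B} \sum_{j=1}^{D}
-M^{(s)}_{b,j} \log M^{(s)}_{b,j},$$

the Breslow-tie negative log partial likelihood plus an entropy penalty
that pushes each mask toward a concise feature subset. The patient index
in the first sum and the step index in the entropy sum are distinct
indices. Because sparsemax can emit exact zeros, the entropy term is
evaluated with $0 \log 0 := 0$, and its gradient is only consumed on the
mask support (the sparsemax Jacobian vanishes off-support).

All forward and backward passes are hand-derived and fully vectorized in
R; no deep-learning runtime is involved. The analytic parameter gradient
of the complete unrolled computation — through the sparsemax projections
and the multiplicative prior chain — agrees with central finite
differences to well below $10^{-5}$ relative error (see the test suite),
which is the foundation for trusting the Adam training loop.

### Design choices in the encoder

Three points where the architecture was genuinely open were resolved as
follows.

* **Mask nonlinearity.** Sparsemax (the Euclidean projection onto the
  simplex) rather than softmax, because the entropy penalty presumes mask
  rows that behave as distributions and because exact zeros are what make
  "this feature was not used" a checkable statement. A softmax variant
  would never produce a literal zero. The implementation is validated
  against a brute-force simplex-projection oracle.
* **No internal batch normalization.** Inputs are Z-scored upstream, and
  the GLU blocks are plain affine maps. Batch-normalization couples
  samples within a batch, which would break two properties the package
  treats as contracts — per-sample determinism at inference and exact
  permutation equivariance of `tabnet_forward()` — and makes analytic
  gradients fragile. With standardized inputs and widths of 8–32 the
  blocks train stably without it.
* **Learned initial attention context.** The first step's attention
  context `a0` is a learned parameter vector shared by all samples,
  rather than a transform of the unmasked input row. The latter (as in
  some encoder variants) leaks gradient through features whose masks are
  zero at every step; with a learned `a0`, the gradient of the log-risk
  with respect to a never-selected feature is exactly zero, which the
  tests verify numerically.

### Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_steps` | 3 | sequential decision steps |
| `width_d`, `width_a` | 16 | decision / attention representation sizes |
| `lambda_sparse` | 1e-3 | entropy penalty weight (dimensionless) |
| `gamma` | 1.3 | prior relaxation; 1 = hard feature exclusion |
| `learning_rate` | 0.01 | Adam step size |
| `patience` | 20 | early-stopping epochs without improvement |
| `stop_frac` | 0.15 | fraction of training rows held for stopping |

The defaults were fixed once for cohorts of a few hundred to a few
thousand patients with 10–50 covariates; `default_grid()` exposes the
searched lattice (steps 3–5, widths 8–32, `lambda_sparse` 1e-4–1e-2) as
configuration. Early stopping monitors the stopping-set partial
likelihood — smooth and cheap — rather than a rank metric; the stopping
subset is carved (event-stratified, seeded) from the training fold so
cross-validation folds stay untouched. Cohorts at this scale are fit
full-batch, so partial-likelihood risk sets are exact rather than
batch-approximated.

## Preprocessing and leakage control

Continuous covariates are Z-scored with the *sample* standard deviation
(n−1), categorical covariates become 0/1 indicators (one-hot with the
first level as reference for multi-level features). Statistics are fitted
on training rows only and applied frozen everywhere else — inside every
cross-validation fold as well, so no held-out row ever influences a
scaling constant. Missing values are a hard error: the package models
cohorts that were curated under complete-case eligibility rules, and
silent imputation would change the estimand. The albumin–bilirubin index
`albi_score()` implements
$0.66 \log_{10}(\text{bilirubin}\ \mu\text{mol/L}) - 0.085\,
\text{albumin g/L}$ for liver-function summaries.

## The synthetic cohort generator

Because clinical cohorts of this kind are private, every downstream
stage is exercised on simulated data with known ground truth. The
generator draws equicorrelated multivariate-normal continuous features
(a stand-in for correlated laboratory panels), Bernoulli(0.5) binary
indicators, assembles a true log-risk from declared linear, threshold,
and pairwise-interaction effects, and samples event times by inversion
from the Weibull proportional-hazards model
$t = \lambda_w(-\log U\, e^{-h})^{1/k}$. Censoring is exponential and
independent of covariates — exactly the assumption the IPCW metrics make
— with its rate solved by root-finding so the expected censoring
fraction (conditional on the drawn event times) hits the target.

The two benchmark conditions used throughout the package's own
evaluation are fixed in `benchmark_config()`: n = 2000, eight continuous
features at pairwise correlation 0.3 plus two binary, Weibull $k = 1.5$,
$\lambda_w = 24$ months, ~30% censoring. The *linear* scenario uses
log-linear effects (0.8, −0.6, 0.4, 0.5), so the classical Cox model is
correctly specified and serves as a ceiling reference. The *nonlinear*
scenario plants a threshold effect (1.6 beyond 0.5 SD), an interaction
(1.0), and a weak linear term (0.4) — strong enough that a log-linear
model is clearly misspecified, which is the regime where an attention
encoder has demonstrable headroom. These sizes were chosen once as
realistic for a single-center oncology cohort and are not revisited.

What the generator does *not* emulate: the marginal skewness and unit
heterogeneity of real laboratory panels, block correlation structure,
competing risks, or informative censoring. Passing tests therefore
demonstrate correctness of the machinery and qualitative model ordering
under proportional hazards with independent censoring — not clinical
performance on any real cohort.

## Evaluation protocol

Discrimination is measured by Harrell's C (pair enumeration with 1/2 for
score ties) and by a cumulative/dynamic AUC at horizon $\tau$ with
inverse-probability-of-censoring weights (cases weighted $1/G(t^-)$,
controls $1/G(\tau)$, $G$ = Kaplan–Meier of the censoring distribution).
Prediction error uses the IPCW Brier score
$$BS(\tau) = \frac1n \sum_i \Big[\frac{S_i^2\,\mathbf 1(t_i \le \tau,
E_i = 1)}{G(t_i^-)} + \frac{(1-S_i)^2\,\mathbf 1(t_i > \tau)}{G(\tau)}
\Big]$$
and its trapezoidal time-average (IBS) over $(0, \tau]$. All four
metrics are validated against brute-force direct-summation oracles in
the test suite. The default horizon is the median follow-up, stated in
every report.

`repeated_cv()` implements repeated K-fold cross-validation
(event-stratified folds, one seed per repeat; the headline protocol is
K = 5 with 10 repeats). Held-out predictions are concatenated across the
K folds and each metric computed once per repeat — per-fold metrics at
n/K ≈ 70–400 are too unstable. Because the Cox log-risk is identified
only up to an additive constant, each fold model's held-out scores are
mean-centered before pooling; without this, cross-fold score pairs
compare arbitrary offsets and the pooled C-index is biased downward for
any encoder with a free intercept. The stability index $\sigma$ is the
sample standard deviation of the per-repeat C-index. Grid search
maximizes mean CV C-index with ties broken by lower $\sigma$, then by
the smaller model.

The package's own acceptance evaluation (and the vignette-scale
examples) run the protocol at 3 repeats × 5 folds on the n = 2000
benchmarks — sizes chosen so the whole evaluation remains a desk-scale
computation while leaving the Monte-Carlo error of the mean CV C-index
near 0.01.

## Risk stratification and clinical-utility outputs

Log-risks map to bounded scores through a rank-based empirical-CDF
normalizer frozen on training data (min–max rescaling is available as a
flag). A bounded score is what makes a fixed published cut-off such as
0.35 transportable; the normalizer choice is declared because a cut-off
is meaningless without its score scale. `optimal_cutoff()` searches the
unique observed scores between the 10th and 90th percentiles for the
log-rank-maximizing threshold under a minimum group-fraction constraint
(default 10%) — and *always* flags that the resulting chi-squared is
inflated by multiplicity. A prespecified cut-off bypasses the search and
is applied verbatim, which is the honest way to carry a development-set
threshold to validation data.

Kaplan–Meier estimation and the log-rank test delegate to the `survival`
package behind thin surfaces (`km_estimator()`, `logrank_test()`), as do
the censoring-distribution estimates inside the IPCW weights. Decision
curves compute net benefit $TP/n - FP/n \cdot p_t/(1-p_t)$ with
IPCW-weighted true/false positives (naively excluding patients censored
before the horizon would bias net benefit); treat-all and treat-none
references come with the curve, plus an optional stage-only reference
model. Calibration bins patients by predicted survival and compares the
bin mean against the within-bin Kaplan–Meier estimate at the horizon.

## Interpretability

Two complementary views are reported. *Mask importance* is
architecture-native: instance-level importance weights each step's mask
by that step's aggregate rectified decision contribution, and global
importance averages the normalized rows. A feature no mask ever selects
has importance exactly zero. *Sampling attributions* are model-agnostic
Shapley estimates via feature-permutation sampling against training
background rows, applied to the log-risk output (not a survival
probability at a horizon — the log-risk is the quantity the model
optimizes and the one on which additivity is natural). The telescoping
construction makes local accuracy exact by design:
$\sum_j \phi_j + \phi_0 = h(x)$ up to floating-point error, for every
audited patient, with $\phi_0$ the mean prediction over the sampled
background. Hierarchical clustering of high-risk patients uses Ward
linkage on Euclidean distance over standardized features, with k chosen
by mean silhouette over 2–5 when not fixed.

## Numerical notes and degenerate inputs

* The partial likelihood uses a single max-shift log-sum-exp; ties use
  Breslow everywhere (loss, gradient, baseline, linear fitter) so the
  loss and the baseline hazard are mutually consistent. The linear
  fitter's Newton iterations use step-halving and report separation
  through a large-coefficient warning.
* Zero events is an error for the loss (likelihood undefined) and a
  warning plus empty hazard for the Breslow estimator.
* Constant continuous columns are an error at preprocessing; constant
  log-risks are an error at normalization; perfect collinearity is an
  infinite VIF (reported, not a crash) but an error in the Newton fitter.
* `sparsemax` is piecewise linear; its backward pass uses the
  support-restricted Jacobian. Gradient checks sample generic points —
  at support-change kinks the one-sided derivatives differ, which is
  inherent to the projection, not an implementation artifact.
* Seeds are first-class: cohort simulation, parameter initialization,
  stopping-set carving, fold shuffling, subsampling, and attribution
  sampling all take explicit seeds, and fixed seeds give bit-identical
  results in single-threaded R.

## Known limitations

* Pure-R training is practical for tabular clinical cohorts (thousands
  of rows, tens of features) but not for much larger problems.
* No embedding layers for high-cardinality categoricals, no
  self-supervised pretraining, no time-varying covariates, stratified
  baselines, or competing risks.
* The comparator families from the broader benchmarking literature
  (random survival forests, boosted survival models, nearest-neighbor
  survival) are out of scope here; where needed they should come from
  the established packages that implement them.
* The multiplicity warning on searched cut-offs is a flag, not a
  correction; honest inference on a searched threshold needs external
  validation, which the override mechanism supports.

## A worked miniature

```{r example, eval = FALSE}
sc <- simulate_cohort(benchmark_config("nonlinear", n = 600, seed = 1))
split <- random_split(sc$cohort, ratio = 0.75, seed = 1)
pp <- fit_preprocess(split$train)
model <- fit_risk_model(apply_preprocess(split$train, pp), "tabnet",
                        seed = 1, preprocess = pp)
h_val <- predict(model, apply_preprocess(split$holdout, pp))
concordance_index(h_val, split$holdout$time, split$holdout$event)

nm <- risk_normalizer(model$train_log_risk)
strata <- stratify_risk(h_val, split$holdout$time, split$holdout$event, nm)
glance(strata)
autoplot(strata)
```
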