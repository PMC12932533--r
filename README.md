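# tabcox

Interpretable deep survival modeling for tabular clinical cohorts:
a sequential-attention encoder (TabNet-style) with a scalar log-risk head
trained by Cox partial likelihood plus an entropy sparsity penalty on its
attention masks — together with the evaluation, risk-stratification, and
interpretability toolkit such a model needs to be used responsibly.

## Who this is for

Biostatisticians and clinical-ML researchers modeling right-censored
time-to-event outcomes (e.g. overall survival after immunotherapy) from
baseline tabular covariates — demographics, tumor characteristics,
treatment category, laboratory panels — who want nonlinear risk models
that remain auditable: which features each patient's prediction used,
how stable the performance estimate is, and whether a risk cut-off
transports to new data.

## The model

Under proportional hazards, λ(t|x) = λ₀(t)·exp(h_θ(x)). The encoder
builds h_θ(x) over N_steps sequential decision steps: an attentive
transformer projects prior-weighted attention scores through sparsemax
(the Euclidean simplex projection, capable of exact zeros) to a
per-patient feature mask M⁽ⁱ⁾; masked features pass through gated linear
blocks; rectified decision outputs are summed into a linear head.
Training minimizes

    L(θ) = −Σ_{i:E_i=1} [ h_θ(x_i) − log Σ_{j∈R(t_i)} exp(h_θ(x_j)) ]
           + λ_sparse · (1/(N_steps·B)) Σ_steps Σ_b Σ_j −M log M,

the Breslow-ties negative log partial likelihood plus an entropy penalty
that pushes each mask toward a concise feature subset. Forward and
backward passes are hand-derived, fully vectorized R; analytic gradients
match finite differences to ~1e-9 relative. Linear Cox (own
Newton–Raphson, cross-checked against `survival::coxph`) and MLP-Cox
comparators share the same loss machinery. The Breslow baseline hazard
turns log-risks into absolute survival curves S(t|x).

Around the model: leakage-safe Z-score preprocessing, a synthetic
Weibull-PH cohort generator with known ground-truth risk, Harrell C /
IPCW time-dependent AUC / IPCW Brier and integrated Brier score
(all oracle-tested), repeated stratified 5-fold CV with a resampling
stability index σ, grid search, learning curves, Kaplan–Meier and
log-rank inference, optimal-cutoff stratification with multiplicity
flags, decision-curve analysis, calibration curves, coalition-sampling
Shapley attributions with exact local accuracy, and Ward clustering of
high-risk phenotypes. Everything user-facing is data-frame-first with
tibble outputs, `tidy()`/`glance()` methods, and `autoplot()` figures.

## Worked example

```r
library(tabcox)

# a synthetic cohort with threshold + interaction effects (n = 600)
sc <- simulate_cohort(benchmark_config("nonlinear", n = 600, seed = 1))
split <- random_split(sc$cohort, ratio = 0.75, seed = 1)
pp <- fit_preprocess(split$train)

model <- fit_risk_model(apply_preprocess(split$train, pp), "tabnet",
                        seed = 1, preprocess = pp)
h_val <- predict(model, apply_preprocess(split$holdout, pp))
concordance_index(h_val, split$holdout$time, split$holdout$event)
#> [1] 0.7916224

lin <- fit_linear_coxph(split$train)
concordance_index(predict(lin, split$holdout), split$holdout$time,
                  split$holdout$event)
#> [1] 0.6496755

nm <- risk_normalizer(model$train_log_risk)
strata <- stratify_risk(h_val, split$holdout$time, split$holdout$event, nm)
glance(strata)
#> # A tibble: 1 × 6
#>   cutoff searched n_low n_high chisq  p.value
#>    <dbl> <lgl>    <int>  <int> <dbl>    <dbl>
#> 1  0.786 TRUE       115     35  115. 6.46e-27
```

The attention model's holdout concordance (0.79) clearly beats the
misspecified linear Cox fit (0.65) on this nonlinear cohort, and the
searched cut-off separates the holdout into groups whose survival curves
differ at log-rank χ² ≈ 115 (the χ² is flagged as multiplicity-inflated
because the threshold was searched; pass `cutoff =` to apply a
prespecified one instead). `aggregate_importance(model_masks(model, ...))`
and `sampling_attribution(...)` then show which features drove the risk.

## Package layout

- `R/` — cohort ingestion/preprocessing, synthetic cohorts, sparsemax +
  encoder with hand-written backprop, Cox loss/baseline, Newton linear
  Cox, metrics, CV protocol, stratification, interpretability, tidiers,
  plots.
- `tests/testthat/` — unit, property, and oracle-comparison tests.
- `vignettes/attention-cox-methods.Rmd` — the methods vignette: model,
  assumptions, design decisions, numerical choices, limitations.
- `inst/cli/tabcox.R` — `simulate` / `train` / `stratify` / `explain`
  subcommands over the package functions.
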