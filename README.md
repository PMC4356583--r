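# ihtsa

Ensemble discrete-time survival networks for modelling long-term outcome
after heart transplantation, plus everything around them: era-stratified
hot-deck multiple imputation, counterfactual time-dependent hazard ratios,
concordance-driven variable ranking, CART summaries of predicted median
survival, discrimination/calibration metrics, and a seeded organ-allocation
policy simulator. Registry data of this kind are access-restricted, so the
package includes a synthetic registry generator with known ground truth;
every statistical component is testable end-to-end without any external
data.

## The model

Follow-up is partitioned into K right-open intervals. For covariates x the
model predicts the conditional hazard per interval,

    h_k(x) = P(death in interval k | alive at its start),
    S_k(x) = prod_{j<=k} (1 - h_j(x)),

with one partial-logistic network (one hidden sigmoid layer, K sigmoid
outputs) per imputed cohort, trained by full-batch resilient
back-propagation on the masked discrete-time cross-entropy with weight
decay. The committee's hazards are averaged. Time-dependent hazard ratios
are counterfactual: each patient is predicted with a risk variable absent
vs present (0 -> 1 for indicators, +half-IQR for continuous variables), the
per-interval ratios are pooled by geometric mean, and CIs come from a
patient bootstrap. See `vignettes/ihtsa-methods.Rmd` for the full account,
including the conventions and caveats.

## Worked example

```r
library(ihtsa)

# 1. a synthetic registry cohort with a planted effect: VAD HR 1.6
cfg <- generator_config(
  n = 3000,
  true_log_hr = list(vad = log(1.6), donor_age = 0.015),
  time_varying = list(),
  missing_rates = c(creatinine = 0.2),
  seed = 42
)
g <- generate_cohort(cfg)
masked <- inject_missingness(g$cohort, cfg)

# 2. derivation / validation split, hot-deck imputation, committee training
sp  <- split_cohort(masked, c(0.83, 0.17), seed = 1)
imp <- impute_probability(sp$dc, m = 3, seed = 1)
mod <- train_ensemble(imp, K = 10, hidden = 6, seed = 1)

# 3. held-out discrimination
ivc <- impute_probability(sp$ivc, m = 1, seed = 2)$cohorts[[1]]
med <- predicted_median_survival(mod, ivc)
harrell_c(med$median_years, ivc$followup_years, ivc$death)
#> Harrell's C = 0.5966 (95% CI 0.5930-0.6002), 72,366 comparable pairs

# 4. counterfactual hazard ratio for the planted variable
tidy(bootstrap_hr_ci(mod, ivc, "vad", B = 500, seed = 3))
#> # A tibble: 3 x 6
#>   variable increment  time    hr lower upper
#>   <chr>        <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 vad              1     1  1.72  1.65  1.79
#> 2 vad              1     5  1.49  1.44  1.53
#> 3 vad              1    10  1.58  1.53  1.63
```

The C-index says the committee orders held-out survival above chance (0.5;
only two modest effects were planted, so discrimination is intrinsically
limited). The hazard-ratio table recovers the planted VAD effect (true rate
ratio 1.6), with the expected attenuation of interval-probability ratios on
the wider late intervals. `autoplot()` methods
exist for curves, hazard-ratio estimates, rankings and allocation runs, and
`tidy()`/`glance()` follow broom conventions.

Downstream stages follow the same pattern: `rank_variables()` +
`select_model_size()` for backward elimination, `fit_tree()` /
`prune_tree()` / `tree_importance()` for the CART summary,
`run_simulation()` for the allocation policies, and `run_pipeline()` to do
everything in one seeded call. A thin command-line wrapper is installed at
`inst/cli/ihtsa.R`.

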