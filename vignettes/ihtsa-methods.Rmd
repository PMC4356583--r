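---
title: "Ensemble discrete-time survival networks for heart transplantation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble discrete-time survival networks for heart transplantation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihtsa)
```

## The problem

Long-term survival after heart transplantation depends jointly on recipient
condition, donor quality and the compatibility of the pair. Large
multi-institutional registries record tens of covariates per transplant, with
heavy right-censoring (follow-up up to 18 years) and pervasive item-level
missingness. `ihtsa` implements a complete modelling stack for this setting:
a flexible discrete-time hazard model, the imputation scheme that feeds it,
counterfactual hazard-ratio summaries, variable ranking, a CART condensation
of predictions into clinically readable groups, and a policy simulator that
asks what a survival-guided organ-allocation rule would change.

Real transplant registries are access-restricted, so the package ships a
synthetic registry generator with known ground truth; every claim the test
suite makes is a claim about recovery of planted structure, not about any
registry.

## The discrete-time hazard model

Follow-up time is partitioned into $K$ right-open intervals
$[b_{k-1}, b_k)$. The model predicts, for a covariate vector $x$, the
conditional hazard

$$h_k(x) = \Pr(\text{death in interval } k \mid \text{alive at } b_{k-1}),$$

with survival $S_k(x) = \prod_{j \le k} (1 - h_j(x))$. A record dying in
interval $k$ contributes Bernoulli targets $(0, \dots, 0, 1)$ over intervals
$1..k$; a record censored inside interval $k$ contributes $(0, \dots, 0)$
over intervals $1..k-1$ and nothing for the partial interval. Censoring
exactly on a boundary counts the preceding interval as fully survived — on
administratively censored data the last interval's risk set would otherwise
be emptied of survivors and its hazard forced to 1.

Each committee member is a partial-logistic artificial neural network
(PLANN-family): one hidden layer of logistic-sigmoid units and $K$
logistic-sigmoid outputs, one hazard per interval. The masked cross-entropy

$$\mathcal{L} = -\!\!\sum_{i,\,k \in \text{at-risk}(i)}\!\!
  \left[d_{ik}\log h_k(x_i) + (1-d_{ik})\log(1-h_k(x_i))\right]
  + \lambda \lVert W \rVert^2$$

is the exact discrete-time survival likelihood; intervals outside a record's
at-risk prefix contribute nothing. Weight decay $\lambda$ applies to
connection weights, not biases.

Training is full-batch resilient back-propagation: each weight keeps its own
step size, multiplied by $\eta^+ = 1.2$ on gradient-sign agreement and
$\eta^- = 0.5$ on disagreement (bounded in $[10^{-6}, 50]$, initial step
0.01), with the sign-flipped gradient suppressed for one step. Because rprop
steps are not monotone, the best weights seen are retained; the *accepted*
loss sequence is nonincreasing by construction. Output biases are
initialized at the logit of the pooled per-interval hazard, which starts the
optimizer at the covariate-free life-table model; remaining weights start
small-uniform under the training seed, so training is fully deterministic
given data and seed.

### Design choices that were genuinely open

* **Architecture.** "$K$ time intervals" can mean $K$ output nodes or
  Biganzoli's time-replicated single-output design. We use $K$ output
  nodes: it matches the published input/hidden/interval accounting, needs
  one forward pass per record, and lets intervals share hidden features.
* **Grid placement.** Boundaries sit at equal-probability (type 7) quantiles
  of observed follow-up, balancing at-risk counts per interval; duplicated
  boundaries (heavily tied follow-up) merge with a warning.
* **Ensemble aggregation.** Member hazards are combined by arithmetic mean,
  which keeps the aggregate a valid hazard in $(0,1)$; members differ by
  imputation draw *and* initialization seed (base seed + member index).
* **Censoring convention.** A partially observed interval yields no target —
  the standard discrete-time treatment; the alternative (counting the
  partial interval as survived) biases hazards downward.

## Cohorts, design matrices, imputation

A cohort is a tibble, one row per transplant, against a fixed column
dictionary (`ihtsa_schema()`, shipped as `inst/extdata/schema.yaml`):
recipient covariates, donor covariates, `followup_years`, `death`, and the
transplant `era` (4 five-year strata). Missing cells are `NA`; `era`,
`followup_years` and `death` may never be missing. Multi-level categoricals
are dichotomized to reference-coded indicators (blood groups, diagnosis,
era, HLA-DR mismatch); continuous columns are standardized with statistics
frozen at fit time; the recipient/donor weight ratio is appended (a height
ratio only when a pass-through donor height column exists — the standard
dictionary has none).

Missing data are completed by **era-stratified probability (hot-deck)
imputation**: each missing cell is replaced by a uniform draw from the
observed values of that variable among other records in the same era
stratum, independently per cell and per imputation. The $M$ completed
cohorts (default 10) are combined through the prediction ensemble — one
network per imputation — rather than through Rubin's-rules coefficient
pooling, which has no analogue for a committee of networks. Per-cell rather
than whole-donor-record draws are used; the joint hot-deck variant is not
implemented. Nearest-neighbour imputation and case-wise deletion are known
alternatives that generalized worse in registry use and are deliberately
absent.

## Counterfactual time-dependent hazard ratios

For a risk variable $v$ and every patient $i$, the model is evaluated twice:
with $v$ "absent" and "present", all else fixed. For indicators this is
$0 \to 1$ regardless of the observed value; for an indicator column of a
multi-level categorical, "absent" is the reference level (sibling indicators
zeroed); for continuous variables, observed $\to$ observed + increment,
where the increment is **half the interquartile range** of the training
cohort (rounded half-up to the variable's native unit for reporting — e.g.
a creatinine step of 22 µmol/l and a donor-age step of 11 years under the
registry-style marginals). The per-interval ratio
$h_k^{\text{present}}/h_k^{\text{absent}}$ (hazards floored at $10^{-8}$) is
aggregated over patients by the geometric mean, and percentile confidence
intervals come from resampling patients with replacement ($B = 1000$ by
default, configurable to registry-scale 10,000).

Two properties of this estimator deserve emphasis:

* **Discretization attenuation.** The quantity estimated is a ratio of
  interval *probabilities*, not of continuous-time rates. If the true rate
  ratio is 2 and an interval carries cumulative baseline hazard $\Lambda$,
  the interval-probability ratio is $(1-e^{-2\Lambda})/(1-e^{-\Lambda}) < 2$,
  e.g. $\approx 1.86$ at $\Lambda = 0.15$. On coarse grids this attenuation
  is visible; at the registry configuration ($K = 25$ over 18 years) it is
  small. Recovery tests therefore run at $K = 10$ or finer.
* **What the bootstrap covers.** Resampling patients under a *fixed* fitted
  model propagates the between-patient spread of the model's HR function
  into the CI. It does not propagate the model's own training/sampling
  error, which at desk-scale sample sizes is the dominant error term; a CI
  that covered the generating truth at nominal rate would require refitting
  the model inside each resample, which the $B = 10{,}000$ registry-scale
  choice rules out computationally. The acceptance suite measures this
  honestly: the point estimates recover the planted effect, while the
  fixed-model bootstrap CI under-covers the generator truth by construction.
  Treat the intervals as describing patient-population uncertainty of the
  fitted model, not parameter uncertainty.

## Variable ranking and model-size selection

Backward elimination, with the recipient–donor match variables (blood
groups, body size, sex, age) exempt as mandatory: each round trains the
$k$-fold committee once, then scores every candidate variable by the drop in
cross-validated C-index when its standardized design columns are set to
their neutral value (0) in the validation matrices; the cheapest-to-remove
variable is eliminated and the procedure repeats. This follows the two-step
scheme in which omissions are scored against the round's trained model; an
exhaustive retrain-per-candidate mode (`mode = "retrain"`) is available but
is $O(p^2)$ trainings. `select_model_size()` returns the smallest subset
whose trajectory C-index is within a tolerance (default 0.002) of the
maximum.

## CART summary and leaf validation

A regression tree (`rpart`, ANOVA splitting, no surrogates) is fitted to the
model's predicted median survival — with every record's era reset to the
latest stratum first, so the tree describes expected survival under current
practice. Weakest-link cost-complexity pruning (reference setting 0.0035)
controls size. Variable importance is the sum of within-node SSE reductions
of a variable's primary splits divided by the root SSE, so values read as
"proportion of variability accounted for" and sum to the tree's explained
variance. Leaf groups are validated by routing derivation and validation
records to leaves and comparing observed Kaplan–Meier curves per leaf
(log-rank).

## Evaluation metrics

* **Harrell's C**: pairs usable iff the shorter observed time is an event;
  the longer survivor should carry the higher predicted score (we use
  predicted median survival); score ties count ½. Verified against $O(n^2)$
  brute-force enumeration and `survival::concordance`.
* **Somers'-D comparison** of two C-indices on the same cohort: paired
  leave-one-out jackknife of $D = 2C - 1$, two-sided normal test.
* **AUROC** for one-year mortality (death within 1 year vs alive at 1 year;
  censored-alive-before-1-year records excluded and counted) with DeLong
  structural-component variance and the paired DeLong test; verified against
  `pROC`.
* **Hosmer–Lemeshow**: equal-count risk deciles, ties to the lower group,
  $\chi^2 = \sum (O-E)^2 / (E(1-E/n_g))$. Degrees of freedom are $g-2$ for
  in-sample use (the classical convention) and $g$ when the predictions were
  produced without fitting to the evaluated outcomes (`external = TRUE`);
  using $g-2$ on external data inflates the type-I error to about 0.10 at
  $g = 10$, which is exactly what a size simulation shows.
* **Kaplan–Meier / log-rank** are delegated to the survival package.

## The synthetic registry generator

`generator_config()` encodes what the generator emulates: continuous
marginals are log-normal fits to the three printed quartiles of the
registry-style summary tables (e.g. creatinine 88/106/132 µmol/l, donor age
22/34/44 years), categorical frequencies match the printed percentages, and
effects are planted on the continuous-time hazard
$\lambda_0(t)\,e^{\mathrm{lp}(t)}$ with a piecewise-constant baseline
(default: 0.17/yr in the first post-transplant year, 0.045/yr thereafter —
roughly 16% first-year mortality and an 11-year median for a median
patient). Time-varying effects switch at a changepoint (defaults mirror the
qualitative registry pattern: mechanical support dominates early, recipient
age weighs late). Censoring is administrative at 18 years plus an
independent exponential (rate 0.08/yr) standing in for staggered accrual.
Missingness is MCAR or MAR(era).

What the generator does **not** emulate — and hence what green tests do not
establish about registry data: covariate correlations (off by default; no
joint distribution is published), center effects, reporting lags, era drift
in covariate distributions, and informative censoring. The sample sizes in
the tests (2,000–5,000) are far below registry scale, so all acceptance
bands are recovery bands, not registry reproductions.

## Numerical and reproducibility choices

* Every stochastic operation draws from a stream derived from
  `(base seed, label)` (`seed_stream()`), so adding a pipeline stage never
  shifts another stage's draws; the caller's global RNG state is always
  restored. Derived seeds stay below $2^{31}$.
* Hazards are clamped to $[10^{-12}, 1-10^{-12}]$ inside the loss and
  floored at $10^{-8}$ before ratio formation.
* Median survival interpolates the piecewise-linear survival curve; a curve
  ending above 0.5 is extrapolated with the final interval's constant rate
  and flagged; a zero-hazard tail is capped at the grid horizon.
* The allocation simulator uses common random numbers by default (shared
  donor, initial-list and replacement streams; per-policy tie-break
  streams), so policy contrasts are not sampling noise; a
  paper-style mode randomizing one policy per donor is available
  (`crn = FALSE`). Ischemia time for hypothetical pairs — unknown before
  transplant — is set to the pool median.
* Models serialize to versioned JSON at full precision; a reloaded model
  reproduces predictions to ~1e-15 relative error.

## Problem sizes used by the test suite

The acceptance checks run at deliberately desk-scale sizes chosen once: the
life-table oracle at $n = 5000$, $K = 5$; proportional-hazards recovery at
$n = 2000$, $K = 10$ over 300 seeded runs; time-varying recovery at
$n = 5000$, $K = 10$; ranking recovery at $n = 3000$, $M = 3$, 3 folds, 20
variables over 5 seeds; the allocation study at a 50-patient waiting list
with 1,000 donor draws over 10 seeds; and the end-to-end pipeline at
$n = 2000$, $M = 3$, $K = 10$, 6 hidden nodes. The registry-scale
configuration (43 inputs, 18 hidden nodes, 25 intervals, 10 members,
$B = 10{,}000$) is the package default where a default is needed but is not
exercised by the tests.

## Known limitations

* No competing risks, no GPU training, no alternative losses.
* The fixed-model bootstrap CI limitation discussed above.
* Comparator risk scores (donor risk indices etc.) are not built in; any
  external per-patient score can be compared via `compare_c()` /
  `delong_test()`.
* The allocation simulator models no waiting-list mortality or arrival
  process — registries do not collect these — so its outputs compare
  policies, not absolute system throughput.
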