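# End-to-end pipeline: generate -> impute -> train -> evaluate -> hazard
# ratios -> tree -> allocation, under one base seed with per-stage derived
# streams, so adding or removing a stage never shifts another stage's draws.

#' Configure an end-to-end pipeline run
#'
#' @param n Synthetic cohort size.
#' @param m Number of imputations / ensemble members.
#' @param K Time intervals.
#' @param hidden Hidden nodes.
#' @param decay Weight decay.
#' @param missing_rates Per-variable missingness injected before imputation.
#' @param hr_variables Design columns for hazard-ratio estimation.
#' @param hr_B Bootstrap resamples for HR confidence intervals.
#' @param tree_cc_alpha Cost-complexity parameter for pruning.
#' @param tree_min_leaf Minimum records per leaf.
#' @param alloc_nw,alloc_draws Waiting-list size and donor draws (set
#'   `alloc_draws = 0` to skip the allocation stage).
#' @param split_fractions Derivation/validation split.
#' @param control A [rprop_control()].
#' @param seed Base seed.
#' @param out_dir Optional directory for artifacts (CSV/JSON); `NULL` keeps
#'   everything in memory.
#' @return A `ihtsa_run_config` list.
#' @export
run_config <- function(n = 2000, m = 3, K = 10, hidden = 6, decay = 1e-4,
                       missing_rates = c(creatinine = 0.15, pvr = 0.2, spp = 0.15),
                       hr_variables = c("donor_age", "creatinine", "ventilator"),
                       hr_B = 200, tree_cc_alpha = 0.0035, tree_min_leaf = 50,
                       alloc_nw = 25, alloc_draws = 200,
                       split_fractions = c(0.83, 0.17),
                       control = rprop_control(), seed = 1, out_dir = NULL) {
  structure(as.list(environment()), class = "ihtsa_run_config")
}

#' Run the full pipeline
#'
#' Executes generate -> impute -> train -> evaluate -> hazard ratios ->
#' tree -> allocate as configured and returns all artifacts; when
#' `config$out_dir` is set, tabular artifacts are written as CSV, the model
#' and run metadata as JSON, and a manifest lists every file with the config
#' hash.
#'
#' @param config An [run_config()].
#' @return A list of stage artifacts: `cohort`, `truth`, `split`,
#'   `imputations`, `model`, `evaluation`, `hazard_ratios`, `tree`,
#'   `allocation`, `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "ihtsa_run_config"))
  seed <- config$seed
  gen_cfg <- generator_config(
    n = config$n,
    missing_rates = config$missing_rates,
    seed = seed_stream(seed, "stage_generate")
  )
  gen <- generate_cohort(gen_cfg)
  masked <- inject_missingness(gen$cohort, gen_cfg)
  split <- split_cohort(masked, config$split_fractions,
    seed = seed_stream(seed, "stage_split")
  )
  imput <- impute_probability(split$dc,
    m = config$m,
    seed = seed_stream(seed, "stage_impute")
  )
  model <- train_ensemble(imput,
    K = config$K, hidden = config$hidden,
    decay = config$decay, control = config$control,
    seed = seed_stream(seed, "stage_train") %% 100000
  )
  # validation-cohort evaluation on a single imputation of the IVC
  ivc <- impute_probability(split$ivc,
    m = 1,
    seed = seed_stream(seed, "stage_impute_ivc")
  )$cohorts[[1]]
  curves <- predict_curve(model, ivc)
  med <- median_survival(curves)
  cidx <- harrell_c(med$median_years, ivc$followup_years, ivc$death)
  s1 <- survival_at(curves, 1)
  lab <- one_year_labels(ivc$followup_years, ivc$death)
  risk1 <- 1 - s1$survival
  roc <- auroc(risk1[lab$keep], lab$labels)
  hl <- hosmer_lemeshow(risk1[lab$keep], lab$labels, external = TRUE)
  recal <- recalibrate_logistic(risk1[lab$keep], lab$labels)
  evaluation <- list(
    c_index = cidx, auroc = roc, hosmer_lemeshow = hl,
    recalibration = recal, excluded_one_year = lab$n_excluded
  )
  hrs <- purrr::map(
    config$hr_variables,
    ~ bootstrap_hr_ci(model, ivc, .x,
      B = config$hr_B,
      seed = seed_stream(seed, paste0("stage_hr_", .x))
    )
  )
  names(hrs) <- config$hr_variables
  dc1 <- imput$cohorts[[1]]
  med_dc <- predicted_median_survival(model, dc1, era_adjust = TRUE)
  feat <- dc1[, setdiff(
    model$variables, c("era")
  ), drop = FALSE]
  tree <- prune_tree(
    fit_tree(feat, med_dc$median_years, min_leaf = config$tree_min_leaf),
    cc_alpha = config$tree_cc_alpha
  )
  allocation <- NULL
  if (config$alloc_draws > 0) {
    allocation <- run_simulation(ivc,
      nw = min(config$alloc_nw, nrow(ivc) - 1),
      n_donor_draws = config$alloc_draws,
      policies = c("ihtsa", "clinical", "random"),
      model = model, seed = seed_stream(seed, "stage_alloc")
    )
  }
  artifacts <- list(
    cohort = gen$cohort, truth = gen$truth, split = split,
    imputations = imput, model = model, evaluation = evaluation,
    hazard_ratios = hrs, tree = tree, allocation = allocation
  )
  if (!is.null(config$out_dir)) {
    artifacts$manifest <- write_artifacts(artifacts, config)
  }
  artifacts
}

write_artifacts <- function(artifacts, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  cfg_hash <- rlang::hash(cfg_for_hash)
  files <- character(0)
  save_csv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    readr::write_csv(df, p)
    files <<- c(files, p)
  }
  save_csv(artifacts$cohort, "cohort.csv")
  save_csv(artifacts$truth, "truth.csv")
  p_model <- file.path(config$out_dir, "model.json")
  write_model(artifacts$model, p_model)
  files <- c(files, p_model)
  hr_tab <- dplyr::bind_rows(lapply(artifacts$hazard_ratios, as_tibble))
  save_csv(hr_tab, "hazard_ratios.csv")
  ev <- artifacts$evaluation
  save_csv(
    tibble(
      metric = c("c_index", "auroc", "hl_p", "recal_slope", "recal_intercept"),
      value = c(
        ev$c_index$c, ev$auroc$auc, ev$hosmer_lemeshow$p_value,
        ev$recalibration$slope, ev$recalibration$intercept
      )
    ),
    "evaluation.csv"
  )
  if (!is.null(artifacts$allocation)) {
    save_csv(artifacts$allocation$summary, "allocation.csv")
  }
  manifest <- tibble(
    file = basename(files),
    config_hash = cfg_hash
  )
  save_csv(manifest, "manifest.csv")
  manifest
}
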