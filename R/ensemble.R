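# The committee ensemble: one hazard network per imputed cohort, each with
# its own preprocessing statistics, sharing one time grid. Ensemble hazards
# are the arithmetic mean of member hazards (keeps them in (0,1)); survival
# is the cumulative product of (1 - hazard).

#' Train a committee ensemble over an imputation set
#'
#' Trains one discrete-time hazard network per imputed cohort (member seed =
#' base seed + member index), with a shared time grid built once from the
#' first imputation's follow-up (follow-up is never imputed, so the grid is
#' identical across imputations). Preprocessing statistics (standardization,
#' reference coding, half-IQR increments) are fitted per member on its own
#' cohort.
#'
#' @param imputation_set An [impute_probability()] result, or a list of
#'   complete cohort tibbles.
#' @param variables Model variables (default: all covariates).
#' @param K Number of time intervals (default 25).
#' @param hidden Hidden nodes per member (default 18).
#' @param decay Weight-decay coefficient.
#' @param control A [rprop_control()].
#' @param reference_levels Passed to [build_design()].
#' @param seed Base seed.
#' @return An `ihtsa_ensemble`: `members` (networks), `designs` (per-member
#'   `ihtsa_design`), `grid`, `variables`, `aggregation`.
#' @export
train_ensemble <- function(imputation_set, variables = NULL, K = 25,
                           hidden = 18, decay = 1e-4,
                           control = rprop_control(),
                           reference_levels = NULL, seed = 1) {
  cohorts <- if (inherits(imputation_set, "ihtsa_imputation_set")) {
    imputation_set$cohorts
  } else if (is.data.frame(imputation_set)) {
    list(imputation_set)
  } else {
    imputation_set
  }
  grid <- build_time_grid(cohorts[[1]], K = K)
  members <- vector("list", length(cohorts))
  designs <- vector("list", length(cohorts))
  for (m in seq_along(cohorts)) {
    co <- cohorts[[m]]
    designs[[m]] <- build_design(co,
      variables = variables,
      reference_levels = reference_levels
    )
    targets <- make_targets(co, grid)
    members[[m]] <- tryCatch(
      train_network(designs[[m]]$x, targets,
        hidden = hidden, decay = decay,
        control = control, seed = seed + m
      ),
      error = function(e) {
        abort(paste0("training failed for ensemble member ", m, ": ", conditionMessage(e)),
          class = "ihtsa_training_error"
        )
      }
    )
  }
  structure(
    list(
      members = members, designs = designs, grid = grid,
      variables = designs[[1]]$variables,
      aggregation = "mean_hazard", seed = seed
    ),
    class = "ihtsa_ensemble"
  )
}

#' @export
print.ihtsa_ensemble <- function(x, ...) {
  cat(
    "<ihtsa_ensemble> ", length(x$members), " members, ",
    x$members[[1]]$input_dim, " inputs, ", x$members[[1]]$hidden,
    " hidden nodes, ", x$grid$K, " time intervals\n",
    sep = ""
  )
  invisible(x)
}

# n x K matrix of ensemble (mean) hazards for a complete cohort, or raw
# member hazards when member = an index.
ensemble_hazards <- function(model, cohort, member = NULL) {
  idx <- member %||% seq_along(model$members)
  acc <- NULL
  for (m in idx) {
    x <- design_transform(model$designs[[m]], cohort)
    h <- predict_hazard(model$members[[m]], x)
    acc <- if (is.null(acc)) h else acc + h
  }
  acc / length(idx)
}

survival_from_hazard <- function(h) {
  if (is.null(dim(h))) h <- matrix(h, nrow = 1)
  t(apply(1 - h, 1, cumprod))
}

#' Predict per-interval hazards and survival curves
#'
#' Ensemble prediction for every record of a (complete) cohort: the
#' per-interval hazard is the arithmetic mean of the member hazards; the
#' survival curve is the cumulative product of (1 - hazard). Deterministic.
#'
#' @param model An `ihtsa_ensemble`.
#' @param cohort A complete cohort tibble (all model variables present).
#' @return An `ihtsa_curves` object: `boundaries`, `hazard` (n x K),
#'   `survival` (n x K).
#' @export
predict_curve <- function(model, cohort) {
  h <- ensemble_hazards(model, cohort)
  structure(
    list(
      boundaries = model$grid$boundaries,
      hazard = h,
      survival = survival_from_hazard(h)
    ),
    class = "ihtsa_curves"
  )
}

#' @export
print.ihtsa_curves <- function(x, ...) {
  cat(
    "<ihtsa_curves> ", nrow(x$hazard), " records over ",
    ncol(x$hazard), " intervals\n",
    sep = ""
  )
  invisible(x)
}

#' Median predicted survival of each curve
#'
#' The first time the piecewise-linear survival curve crosses 0.5,
#' interpolated within the crossing interval. If the curve ends above 0.5,
#' the value is extrapolated beyond the grid by converting the final
#' interval's hazard to a constant continuous-time rate, and flagged; a
#' zero-hazard tail is capped at the grid horizon (also flagged).
#'
#' @param curves An `ihtsa_curves` from [predict_curve()].
#' @return A tibble with `record` (row index), `median_years`,
#'   `extrapolated`.
#' @export
median_survival <- function(curves) {
  b <- curves$boundaries
  S <- curves$survival
  K <- ncol(S)
  n <- nrow(S)
  med <- numeric(n)
  extra <- logical(n)
  for (i in seq_len(n)) {
    s_full <- c(1, S[i, ])
    k <- which(s_full <= 0.5)[1]
    if (!is.na(k)) {
      if (s_full[k] == 0.5) {
        med[i] <- b[k]
      } else {
        s0 <- s_full[k - 1]
        s1 <- s_full[k]
        med[i] <- b[k - 1] + (b[k] - b[k - 1]) * (s0 - 0.5) / (s0 - s1)
      }
    } else {
      extra[i] <- TRUE
      h_last <- curves$hazard[i, K]
      width <- b[K + 1] - b[K]
      rate <- -log(1 - h_last) / width
      if (rate <= 0 || !is.finite(rate)) {
        med[i] <- b[K + 1] # zero-hazard tail: horizon cap
      } else {
        med[i] <- b[K + 1] + log(S[i, K] / 0.5) / rate
      }
    }
  }
  tibble(record = seq_len(n), median_years = med, extrapolated = extra)
}

#' Survival probability at given times
#'
#' Piecewise-linear interpolation of each survival curve (consistent with
#' [median_survival()]); `t = 0` gives 1 and grid boundaries give the exact
#' `S_k`. Times beyond the grid are extrapolated with the final interval's
#' constant-rate tail and flagged.
#'
#' @param curves An `ihtsa_curves`.
#' @param t Numeric vector of times in years.
#' @return A tibble with `record`, `time`, `survival`, `extrapolated`.
#' @export
survival_at <- function(curves, t) {
  if (any(t < 0)) abort("t must be >= 0", class = "ihtsa_argument_error")
  b <- curves$boundaries
  K <- ncol(curves$survival)
  n <- nrow(curves$survival)
  out <- purrr::map_dfr(t, function(tt) {
    if (tt <= b[K + 1]) {
      s <- vapply(seq_len(n), function(i) {
        s_full <- c(1, curves$survival[i, ])
        stats::approx(b, s_full, xout = tt, method = "linear")$y
      }, numeric(1))
      tibble(record = seq_len(n), time = tt, survival = s, extrapolated = FALSE)
    } else {
      h_last <- curves$hazard[, K]
      width <- b[K + 1] - b[K]
      rate <- -log(1 - h_last) / width
      s <- curves$survival[, K] * exp(-rate * (tt - b[K + 1]))
      tibble(record = seq_len(n), time = tt, survival = s, extrapolated = TRUE)
    }
  })
  out
}

#' Era-adjusted predicted median survival per record
#'
#' Convenience wrapper: optionally resets every record's transplant era to
#' the most recent level before prediction (used when summarizing expected
#' survival under current practice, e.g. for the CART stage), then returns
#' the predicted median survival.
#'
#' @param model An `ihtsa_ensemble`.
#' @param cohort A complete cohort.
#' @param era_adjust Reset `era` to the latest level first? Default `FALSE`.
#' @return The [median_survival()] tibble.
#' @export
predicted_median_survival <- function(model, cohort, era_adjust = FALSE) {
  if (era_adjust && "era" %in% names(cohort)) {
    cohort$era <- ERA_LEVELS[length(ERA_LEVELS)]
  }
  median_survival(predict_curve(model, cohort))
}

#' Cross-validated selection of hidden nodes and weight decay
#'
#' Seeded k-fold cross-validation over a grid of hidden-layer sizes and
#' weight-decay values. Each grid point is scored by the mean validation
#' metric across folds: Harrell's C of predicted median survival against
#' observed follow-up (the default), or the masked cross-entropy per target.
#' Ties break toward smaller `hidden`, then larger `decay`. The selected
#' configuration is refit on the full data.
#'
#' @param cohort A complete cohort tibble.
#' @param variables Model variables.
#' @param K Time intervals.
#' @param hidden_grid,decay_grid Candidate values (nonempty).
#' @param folds Number of folds (default 5, >= 2).
#' @param metric `"cindex"` (maximized) or `"loss"` (minimized).
#' @param control A [rprop_control()].
#' @param seed Integer seed (fold assignment and member inits).
#' @return A list: `best_hidden`, `best_decay`, `metrics` (tibble of fold
#'   means per grid point), `fold_metrics`, and `model` (an
#'   `ihtsa_ensemble` with a single member refit on all data).
#' @export
cross_validate <- function(cohort, variables = NULL, K = 10,
                           hidden_grid = c(2, 4, 8), decay_grid = c(1e-4),
                           folds = 5, metric = c("cindex", "loss"),
                           control = rprop_control(), seed = 1) {
  metric <- match.arg(metric)
  if (folds < 2) abort("folds must be >= 2", class = "ihtsa_argument_error")
  if (length(hidden_grid) == 0 || length(decay_grid) == 0) {
    abort("grids must be nonempty", class = "ihtsa_argument_error")
  }
  n <- nrow(cohort)
  grid <- build_time_grid(cohort, K = K)
  fold_of <- make_folds(cohort, folds, seed)
  grid_pts <- tidyr::expand_grid(hidden = hidden_grid, decay = decay_grid)
  fold_metrics <- purrr::pmap_dfr(grid_pts, function(hidden, decay) {
    purrr::map_dfr(seq_len(folds), function(f) {
      tr <- cohort[fold_of != f, , drop = FALSE]
      va <- cohort[fold_of == f, , drop = FALSE]
      design <- build_design(tr, variables = variables)
      net <- train_network(design$x, make_targets(tr, grid),
        hidden = hidden, decay = decay, control = control,
        seed = seed_stream(seed, paste0("cv", f))
      )
      xv <- design_transform(design, va)
      h <- predict_hazard(net, xv)
      value <- if (metric == "cindex") {
        curves <- structure(
          list(
            boundaries = grid$boundaries, hazard = h,
            survival = survival_from_hazard(h)
          ),
          class = "ihtsa_curves"
        )
        score <- median_survival(curves)$median_years
        harrell_c(score, va$followup_years, va$death)$c
      } else {
        tg <- make_targets(va, grid)
        hc <- pmin(pmax(h, 1e-12), 1 - 1e-12)
        -sum(tg$at_risk * (tg$event * log(hc) +
          (1 - tg$event) * log(1 - hc))) / sum(tg$at_risk)
      }
      tibble(hidden = hidden, decay = decay, fold = f, value = value)
    })
  })
  metrics <- fold_metrics |>
    dplyr::group_by(.data$hidden, .data$decay) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ord <- if (metric == "cindex") {
    order(-metrics$value, metrics$hidden, -metrics$decay)
  } else {
    order(metrics$value, metrics$hidden, -metrics$decay)
  }
  best <- metrics[ord[1], ]
  model <- train_ensemble(list(cohort),
    variables = variables, K = K,
    hidden = best$hidden, decay = best$decay, control = control, seed = seed
  )
  list(
    best_hidden = best$hidden, best_decay = best$decay,
    metrics = metrics, fold_metrics = fold_metrics, model = model
  )
}

# Seeded fold assignment; a fold without events is redrawn once, then errors.
make_folds <- function(cohort, folds, seed) {
  n <- nrow(cohort)
  draw <- function(s) {
    with_seed(seed_stream(s, "folds"), {
      sample(rep_len(seq_len(folds), n))
    })
  }
  fold_of <- draw(seed)
  events_per_fold <- vapply(
    seq_len(folds),
    function(f) sum(cohort$death[fold_of == f]), numeric(1)
  )
  if (any(events_per_fold == 0)) {
    fold_of <- draw(seed + 1)
    events_per_fold <- vapply(
      seq_len(folds),
      function(f) sum(cohort$death[fold_of == f]), numeric(1)
    )
    if (any(events_per_fold == 0)) {
      abort("a cross-validation fold has zero events (after one resample)",
        class = "ihtsa_training_error"
      )
    }
  }
  fold_of
}
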