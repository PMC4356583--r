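# Counterfactual time-dependent hazard ratios. For every patient the model
# is evaluated under two conditions of one risk variable -- "absent" and
# "present" (0 -> 1 for indicators; observed -> observed + half-IQR for
# continuous variables; reference level -> level for categorical indicator
# columns) -- with everything else fixed. The per-interval ratio of the two
# predicted hazards is aggregated across patients by the geometric mean, and
# confidence intervals come from a patient-level bootstrap.

# Resolve a user-supplied variable name to the perturbation rule.
hr_perturbation <- function(model, variable, increment = NULL) {
  design <- model$designs[[1]]
  if (variable %in% names(design$levels)) {
    abort(paste0(
      "variable ", variable, " is multi-level; perturb one of its ",
      "indicator columns (e.g. ", paste0(variable, "_<level>"), ")"
    ), class = "ihtsa_argument_error")
  }
  if (!variable %in% design$column_names) {
    abort(paste0(variable, " is not a model input column"),
      class = "ihtsa_argument_error"
    )
  }
  kind <- design$column_kinds[[variable]]
  if (kind == "continuous") {
    inc <- increment %||% unname(design$increments[variable])
    if (is.null(inc) || is.na(inc) || inc == 0) {
      abort(paste0("degenerate (zero) increment for ", variable),
        class = "ihtsa_argument_error"
      )
    }
    if (inc < 0) {
      abort("increment must be > 0", class = "ihtsa_argument_error")
    }
  } else {
    inc <- 1
  }
  # does the column belong to a reference-coded categorical block?
  parent <- NULL
  for (nm in names(design$levels)) {
    levs <- setdiff(design$levels[[nm]]$levels, design$levels[[nm]]$reference)
    cols <- paste0(nm, "_", gsub("[^A-Za-z0-9]+", "_", levs))
    if (variable %in% cols) {
      parent <- list(variable = nm, siblings = setdiff(cols, variable))
      break
    }
  }
  list(kind = kind, increment = inc, parent = parent)
}

# Build the absent/present standardized design matrices for one member.
perturbed_pair <- function(design, cohort, variable, pert) {
  x <- design_transform(design, cohort)
  j <- match(variable, design$column_names)
  x0 <- x
  x1 <- x
  if (pert$kind == "continuous") {
    # increment is in native units; the columns are standardized
    x1[, j] <- x[, j] + pert$increment / design$scales[j]
  } else {
    x0[, j] <- 0
    x1[, j] <- 1
    if (!is.null(pert$parent)) {
      # absent = the reference level: zero the sibling indicators too
      sib <- match(pert$parent$siblings, design$column_names)
      x0[, sib] <- 0
      x1[, sib] <- 0
    }
  }
  list(x0 = x0, x1 = x1)
}

#' Per-patient, per-interval counterfactual hazard ratios
#'
#' For each patient, predicts ensemble hazards with the variable absent and
#' present (all other inputs fixed) and returns the per-interval ratio.
#' Indicators are toggled 0 -> 1 for every patient regardless of the
#' observed value; indicator columns of a multi-level categorical are
#' compared against the reference level (siblings zeroed); continuous
#' columns are shifted by the increment (default: the model's stored
#' half-IQR step, in native units). Hazards are floored at `eps` before
#' division.
#'
#' @param model An `ihtsa_ensemble`.
#' @param cohort A complete cohort tibble.
#' @param variable A design-matrix column name (e.g. `"creatinine"`,
#'   `"ecmo"`, `"recipient_bg_A"`).
#' @param increment Positive step for continuous variables, in native units;
#'   default the design's half-IQR.
#' @param eps Hazard floor before forming ratios (default 1e-8).
#' @return An `ihtsa_hr_matrix`: list with `hr` (n x K matrix), `variable`,
#'   `increment`, `boundaries`.
#' @export
counterfactual_hr <- function(model, cohort, variable, increment = NULL,
                              eps = 1e-8) {
  pert <- hr_perturbation(model, variable, increment)
  acc0 <- NULL
  acc1 <- NULL
  for (m in seq_along(model$members)) {
    pair <- perturbed_pair(model$designs[[m]], cohort, variable, pert)
    h0 <- predict_hazard(model$members[[m]], pair$x0)
    h1 <- predict_hazard(model$members[[m]], pair$x1)
    acc0 <- if (is.null(acc0)) h0 else acc0 + h0
    acc1 <- if (is.null(acc1)) h1 else acc1 + h1
  }
  h0 <- pmax(acc0 / length(model$members), eps)
  h1 <- pmax(acc1 / length(model$members), eps)
  structure(
    list(
      hr = h1 / h0, variable = variable, increment = pert$increment,
      boundaries = model$grid$boundaries
    ),
    class = "ihtsa_hr_matrix"
  )
}

#' Geometric-mean aggregation of per-patient hazard ratios
#'
#' `exp(mean(log HR))` per interval across patients.
#'
#' @param hr_matrix An `ihtsa_hr_matrix` from [counterfactual_hr()], or a
#'   positive numeric matrix (patients x intervals).
#' @return A tibble with `interval`, `t_start`, `t_end` (when available),
#'   `hr`, and `n_patients`.
#' @export
aggregate_hr <- function(hr_matrix) {
  m <- if (inherits(hr_matrix, "ihtsa_hr_matrix")) hr_matrix$hr else as.matrix(hr_matrix)
  if (any(m <= 0)) {
    abort("all hazard ratios must be > 0", class = "ihtsa_argument_error")
  }
  g <- exp(colMeans(log(m)))
  out <- tibble(
    interval = seq_along(g), hr = g, n_patients = nrow(m)
  )
  if (inherits(hr_matrix, "ihtsa_hr_matrix")) {
    b <- hr_matrix$boundaries
    out$t_start <- b[out$interval]
    out$t_end <- b[out$interval + 1]
    out <- out[, c("interval", "t_start", "t_end", "hr", "n_patients")]
  }
  out
}

#' Hazard ratio at requested times
#'
#' Returns the aggregated HR of the interval containing each time; a time on
#' an interval boundary belongs to the right-adjacent interval (half-open
#' convention).
#'
#' @param estimate An `ihtsa_hr_matrix` or the tibble from [aggregate_hr()]
#'   (must carry `t_start`/`t_end`).
#' @param times Times in years (default 1, 5, 10).
#' @return A tibble with `time` and `hr`.
#' @export
hr_at_times <- function(estimate, times = c(1, 5, 10)) {
  if (any(times < 0)) abort("negative time", class = "ihtsa_argument_error")
  agg <- if (inherits(estimate, "ihtsa_hr_matrix")) aggregate_hr(estimate) else estimate
  if (!all(c("t_start", "t_end") %in% names(agg))) {
    abort("estimate lacks interval boundaries", class = "ihtsa_argument_error")
  }
  b <- c(agg$t_start, agg$t_end[nrow(agg)])
  grid <- structure(list(boundaries = b, K = nrow(agg)), class = "ihtsa_time_grid")
  k <- interval_index(grid, times)
  tibble(time = times, hr = agg$hr[k])
}

#' Bootstrap confidence intervals for aggregated hazard ratios
#'
#' Resamples patients with replacement `B` times, recomputes the
#' geometric-mean HR, and reports seeded percentile intervals at the
#' requested times together with the point estimate.
#'
#' @inheritParams counterfactual_hr
#' @param times Reporting times in years.
#' @param B Number of bootstrap resamples (>= 100; default 1000 for
#'   desk-scale runs, configurable up to the registry-scale 10,000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return An `ihtsa_hr_estimate`: tibble with `variable`, `increment`,
#'   `time`, `hr`, `lower`, `upper`, plus attributes `B`, `level`, `seed`,
#'   and the full per-interval aggregate in `attr(, "by_interval")`.
#' @export
bootstrap_hr_ci <- function(model, cohort, variable, increment = NULL,
                            times = c(1, 5, 10), B = 1000, level = 0.95,
                            seed = 1, eps = 1e-8) {
  if (B < 100) abort("B must be >= 100", class = "ihtsa_argument_error")
  hrm <- counterfactual_hr(model, cohort, variable, increment, eps = eps)
  log_hr <- log(hrm$hr)
  n <- nrow(log_hr)
  agg <- aggregate_hr(hrm)
  point <- hr_at_times(hrm, times)
  grid <- structure(
    list(boundaries = hrm$boundaries, K = ncol(log_hr)),
    class = "ihtsa_time_grid"
  )
  k_times <- interval_index(grid, times)
  boot <- with_seed(seed_stream(seed, paste0("boot_", variable)), {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      exp(colMeans(log_hr[idx, k_times, drop = FALSE]))
    }, numeric(length(k_times)))
  })
  boot <- matrix(boot, nrow = length(k_times))
  alpha <- (1 - level) / 2
  out <- tibble(
    variable = variable,
    increment = hrm$increment,
    time = times,
    hr = point$hr,
    lower = apply(boot, 1, quantile, probs = alpha, type = 7),
    upper = apply(boot, 1, quantile, probs = 1 - alpha, type = 7)
  )
  attr(out, "B") <- B
  attr(out, "level") <- level
  attr(out, "seed") <- seed
  attr(out, "by_interval") <- agg
  class(out) <- c("ihtsa_hr_estimate", class(out))
  out
}
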