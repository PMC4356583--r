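# Backward variable elimination ranked by concordance-index degradation.
# Each round trains the k-fold committee once (step I), then scores every
# non-mandatory variable by the drop in cross-validated C-index when that
# variable is neutralized at validation time (step II): the standardized
# column is set to its mean (0), the neutral value. The variable whose
# omission costs least is removed; rounds repeat until only the mandatory
# recipient-donor match variables remain. An exhaustive mode retrains for
# every candidate omission instead.

# Train fold committees once and return a scorer over masked column sets.
fold_committee <- function(cohorts, variables, grid, hidden, decay,
                           control, folds, seed) {
  n <- nrow(cohorts[[1]])
  fold_of <- make_folds(cohorts[[1]], folds, seed)
  fits <- purrr::map(seq_len(folds), function(f) {
    tr_rows <- fold_of != f
    members <- purrr::imap(cohorts, function(co, m) {
      tr <- co[tr_rows, , drop = FALSE]
      design <- build_design(tr, variables = variables)
      net <- train_network(design$x, make_targets(tr, grid),
        hidden = hidden, decay = decay, control = control,
        seed = seed + 97 * f + m
      )
      # validation matrix cached once; candidate omissions only mask columns
      xv <- design_transform(design, co[!tr_rows, , drop = FALSE])
      list(design = design, net = net, xv = xv)
    })
    list(members = members, val_rows = which(!tr_rows))
  })
  list(fits = fits, fold_of = fold_of)
}

# CV C-index with the given design columns zero-masked at validation time.
masked_cv_cindex <- function(committee, cohorts, grid, mask_cols = character(0)) {
  vals <- purrr::map_dbl(committee$fits, function(fold) {
    va_rows <- fold$val_rows
    va <- cohorts[[1]][va_rows, , drop = FALSE]
    acc <- NULL
    for (m in seq_along(fold$members)) {
      mem <- fold$members[[m]]
      xv <- mem$xv
      if (length(mask_cols) > 0) {
        j <- match(mask_cols, mem$design$column_names)
        j <- j[!is.na(j)]
        xv[, j] <- 0
      }
      h <- predict_hazard(mem$net, xv)
      acc <- if (is.null(acc)) h else acc + h
    }
    h <- acc / length(fold$members)
    curves <- structure(
      list(
        boundaries = grid$boundaries, hazard = h,
        survival = survival_from_hazard(h)
      ),
      class = "ihtsa_curves"
    )
    score <- median_survival(curves)$median_years
    harrell_c(score, va$followup_years, va$death)$c
  })
  mean(vals)
}

# design columns produced by a schema variable (indicator blocks expand)
columns_of_variable <- function(design, variable) {
  if (variable %in% design$column_names) {
    return(variable)
  }
  if (variable %in% names(design$levels)) {
    levs <- setdiff(
      design$levels[[variable]]$levels,
      design$levels[[variable]]$reference
    )
    return(paste0(variable, "_", gsub("[^A-Za-z0-9]+", "_", levs)))
  }
  abort(paste0("unknown variable ", variable), class = "ihtsa_argument_error")
}

#' Backward variable elimination by C-index degradation
#'
#' Iterates: (I) train the fold committee on the current variable set; (II)
#' for each non-mandatory variable compute the cross-validated C-index with
#' that variable's design columns neutralized (zero-masked) at validation
#' time; remove the variable whose omission reduces the C-index least (ties
#' by variable list order); repeat until only the mandatory variables
#' remain. With `mode = "retrain"` every candidate omission retrains the
#' committee instead of masking.
#'
#' @param imputation_set An [impute_probability()] result or list of
#'   complete cohorts.
#' @param variables Variables to model (default all covariates).
#' @param mandatory Character vector of variables never eliminated (the
#'   recipient-donor match variables in registry use); must be a strict
#'   subset of `variables`.
#' @param K,hidden,decay,control Network settings for each round's
#'   committee.
#' @param folds Cross-validation folds per round (default 5).
#' @param mode `"mask"` (default; score omissions against the round's
#'   committee) or `"retrain"` (exhaustive).
#' @param seed Integer seed.
#' @return An `ihtsa_ranking`: `elimination_order` (least to most
#'   important), `c_trajectory` (C-index after each removal, starting with
#'   the full model), `deltas` (tibble of per-round removal deltas),
#'   `mandatory`.
#' @export
rank_variables <- function(imputation_set, variables = NULL,
                           mandatory = character(0), K = 10, hidden = 4,
                           decay = 1e-4, control = rprop_control(),
                           folds = 5, mode = c("mask", "retrain"), seed = 1) {
  mode <- match.arg(mode)
  cohorts <- if (inherits(imputation_set, "ihtsa_imputation_set")) {
    imputation_set$cohorts
  } else if (is.data.frame(imputation_set)) {
    list(imputation_set)
  } else {
    imputation_set
  }
  variables <- variables %||%
    schema_var_names(ihtsa_schema(), covariates_only = TRUE)
  if (!all(mandatory %in% variables)) {
    abort("mandatory must be a subset of variables", class = "ihtsa_argument_error")
  }
  rankable <- setdiff(variables, mandatory)
  if (length(rankable) == 0) {
    abort("mandatory set equals the full variable set: nothing to rank",
      class = "ihtsa_argument_error"
    )
  }
  grid <- build_time_grid(cohorts[[1]], K = K)
  current <- variables
  elimination <- character(0)
  trajectory <- numeric(0)
  deltas <- list()
  round <- 0
  while (length(setdiff(current, mandatory)) > 0) {
    round <- round + 1
    committee <- fold_committee(
      cohorts, current, grid, hidden, decay, control, folds,
      seed_stream(seed, paste0("round", round))
    )
    design0 <- committee$fits[[1]]$members[[1]]$design
    c_full <- masked_cv_cindex(committee, cohorts, grid)
    if (round == 1) trajectory <- c_full
    candidates <- setdiff(current, mandatory)
    c_without <- purrr::map_dbl(candidates, function(v) {
      if (mode == "mask") {
        masked_cv_cindex(committee, cohorts, grid,
          mask_cols = columns_of_variable(design0, v)
        )
      } else {
        sub_committee <- fold_committee(
          cohorts, setdiff(current, v), grid, hidden, decay, control, folds,
          seed_stream(seed, paste0("round", round, "_", v))
        )
        masked_cv_cindex(sub_committee, cohorts, grid)
      }
    })
    drop_delta <- c_full - c_without
    pick <- which.min(drop_delta) # ties: first in variable list order
    deltas[[round]] <- tibble(
      round = round, variable = candidates,
      c_full = c_full, c_without = c_without, delta = drop_delta
    )
    elimination <- c(elimination, candidates[pick])
    current <- setdiff(current, candidates[pick])
    trajectory <- c(trajectory, c_without[pick])
  }
  structure(
    list(
      elimination_order = elimination,
      c_trajectory = trajectory,
      deltas = dplyr::bind_rows(deltas),
      mandatory = mandatory,
      variables = variables
    ),
    class = "ihtsa_ranking"
  )
}

#' @export
print.ihtsa_ranking <- function(x, ...) {
  cat(
    "<ihtsa_ranking> ", length(x$elimination_order), " variables ranked (",
    length(x$mandatory), " mandatory exempt)\n",
    sep = ""
  )
  imp <- rev(x$elimination_order)
  cat(
    "most important first: ",
    paste(head(imp, 8), collapse = ", "),
    if (length(imp) > 8) ", ..." else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' Select a model size from the ranking trajectory
#'
#' Returns the smallest variable subset whose cross-validated C-index lies
#' within `tolerance` of the trajectory maximum, always including the
#' mandatory variables.
#'
#' @param ranking An `ihtsa_ranking`.
#' @param tolerance Allowed C-index shortfall from the maximum
#'   (default 0.002).
#' @return Character vector of selected variables (mandatory included).
#' @export
select_model_size <- function(ranking, tolerance = 0.002) {
  traj <- ranking$c_trajectory
  if (length(traj) == 0) abort("empty trajectory", class = "ihtsa_argument_error")
  # trajectory[i] = C-index with (i - 1) variables removed
  best <- max(traj)
  ok <- which(traj >= best - tolerance)
  removals <- max(ok) - 1
  removed <- head(ranking$elimination_order, removals)
  setdiff(ranking$variables, removed)
}
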