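# Era-stratified hot-deck ("probability") imputation. Each missing cell is
# filled, independently per imputation, by a uniform draw from the observed
# values of that variable among the other records of the same stratum. The M
# completed cohorts feed the prediction ensemble; no Rubin's-rules pooling is
# performed because imputations are combined through the committee of
# networks, not through coefficients.

#' Era-stratified probability (hot-deck) imputation
#'
#' Produces `m` completed copies of a cohort. Every missing cell is replaced
#' by a value drawn uniformly at random from the observed values of the same
#' variable among *other* records in the same stratum (default stratifier:
#' transplant era). Draws are independent across cells, variables and
#' imputations. If a stratum holds no observed value for a variable, the draw
#' falls back to the pooled observed values across strata (logged in the
#' result's `fallbacks`).
#'
#' @param cohort A cohort tibble (the stratifier must be complete).
#' @param m Number of imputations (default 10).
#' @param stratify Name of the stratifying column (default `"era"`).
#' @param seed Integer seed; identical seeds give identical imputation sets.
#' @return An object of class `ihtsa_imputation_set`: list with `cohorts`
#'   (list of m complete tibbles), `m`, `strata`, `seed`, and `fallbacks`
#'   (tibble of variable/stratum pairs that required a pooled draw).
#' @export
#' @examples
#' cfg <- generator_config(n = 200, missing_rates = c(creatinine = 0.3), seed = 2)
#' g <- generate_cohort(cfg)
#' masked <- inject_missingness(g$cohort, cfg)
#' imp <- impute_probability(masked, m = 3, seed = 9)
#' length(imp$cohorts)
impute_probability <- function(cohort, m = 10, stratify = "era", seed = 1) {
  if (m < 1) abort("m must be >= 1", class = "ihtsa_argument_error")
  if (!stratify %in% names(cohort)) {
    abort(paste0("stratifier ", stratify, " not found"),
      class = "ihtsa_argument_error"
    )
  }
  if (anyNA(cohort[[stratify]])) {
    abort("stratifier may not contain missing values",
      class = "ihtsa_argument_error"
    )
  }
  strata <- as.character(cohort[[stratify]])
  vars <- names(cohort)[vapply(cohort, anyNA, logical(1))]
  for (v in vars) {
    if (all(is.na(cohort[[v]]))) {
      abort(paste0("variable ", v, " is missing for every record"),
        class = "ihtsa_imputation_error"
      )
    }
  }
  fallbacks <- list()
  cohorts <- with_seed(seed_stream(seed, "impute"), {
    purrr::map(seq_len(m), function(k) {
      out <- cohort
      for (v in vars) {
        x <- cohort[[v]]
        miss_idx <- which(is.na(x))
        for (s in unique(strata[miss_idx])) {
          idx <- miss_idx[strata[miss_idx] == s]
          donors <- x[!is.na(x) & strata == s]
          if (length(donors) == 0) {
            donors <- x[!is.na(x)]
            fallbacks[[length(fallbacks) + 1]] <<-
              tibble(imputation = k, variable = v, stratum = s)
          }
          out[[v]][idx] <- donors[sample.int(length(donors), length(idx),
            replace = TRUE
          )]
        }
      }
      out
    })
  })
  structure(
    list(
      cohorts = cohorts, m = m, strata = stratify, seed = seed,
      fallbacks = if (length(fallbacks)) {
        dplyr::bind_rows(fallbacks)
      } else {
        tibble(
          imputation = integer(), variable = character(),
          stratum = character()
        )
      }
    ),
    class = "ihtsa_imputation_set"
  )
}

#' @export
print.ihtsa_imputation_set <- function(x, ...) {
  cat(
    "<ihtsa_imputation_set> m = ", x$m, ", n = ", nrow(x$cohorts[[1]]),
    ", stratified by ", x$strata, "\n",
    sep = ""
  )
  invisible(x)
}

#' Per-variable missingness report
#'
#' Counts and fractions of missing cells per variable, pooled and by stratum.
#'
#' @param cohort A cohort tibble.
#' @param stratify Optional stratifier column name (default `"era"`); pass
#'   `NULL` for a pooled-only report.
#' @return A tibble with columns `variable`, `stratum` (`"(all)"` for the
#'   pooled rows), `n`, `n_missing`, `fraction`.
#' @export
missingness_report <- function(cohort, stratify = "era") {
  vars <- setdiff(names(cohort), character(0))
  pooled <- purrr::map_dfr(vars, function(v) {
    tibble(
      variable = v, stratum = "(all)", n = nrow(cohort),
      n_missing = sum(is.na(cohort[[v]]))
    )
  })
  out <- pooled
  if (!is.null(stratify) && stratify %in% names(cohort)) {
    strata <- as.character(cohort[[stratify]])
    per <- purrr::map_dfr(unique(strata), function(s) {
      sub <- cohort[strata == s, , drop = FALSE]
      purrr::map_dfr(vars, function(v) {
        tibble(
          variable = v, stratum = s, n = nrow(sub),
          n_missing = sum(is.na(sub[[v]]))
        )
      })
    })
    out <- dplyr::bind_rows(pooled, per)
  }
  dplyr::mutate(out, fraction = .data$n_missing / .data$n)
}
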