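# Cohort data model: the column dictionary, CSV I/O, the derivation /
# validation split and half-IQR increments. A cohort is an ordinary tibble,
# one row per transplant; missing covariate cells are NA. `followup_years`,
# `death` and `era` are mandatory and may never be missing (era is the
# imputation stratifier).

# Protected columns that carry the outcome / stratification and must never
# be masked or imputed.
PROTECTED_COLUMNS <- c("followup_years", "death", "era")

ERA_LEVELS <- c("1991-1995", "1996-2000", "2001-2005", "2006-2010")
BLOOD_GROUPS <- c("A", "AB", "B", "O")
DIAGNOSIS_LEVELS <- c(
  "ischemic_cm", "non_ischemic_cm", "congenital",
  "graft_failure", "valvular", "other"
)
SEX_LEVELS <- c("female", "male")

#' Column dictionary for transplant cohorts
#'
#' One row per column of a cohort CSV: the column name, its kind
#' (`continuous`, `indicator` or `categorical`), the admissible levels for
#' categorical columns, the measurement unit, and whether the column belongs
#' to the recipient, the donor, or the outcome. This dictionary is the single
#' source of truth for validation, design-matrix construction, the synthetic
#' generator and imputation.
#'
#' @return A tibble with columns `name`, `kind`, `levels` (list-column),
#'   `unit`, `role`, `maskable`.
#' @export
#' @examples
#' ihtsa_schema()
ihtsa_schema <- function() {
  tribble_row <- function(name, kind, levels, unit, role, maskable) {
    tibble(
      name = name, kind = kind, levels = list(levels),
      unit = unit, role = role, maskable = maskable
    )
  }
  dplyr::bind_rows(
    tribble_row("recipient_age", "continuous", NULL, "years", "recipient", TRUE),
    tribble_row("recipient_sex", "categorical", SEX_LEVELS, "", "recipient", TRUE),
    tribble_row("recipient_height", "continuous", NULL, "cm", "recipient", TRUE),
    tribble_row("recipient_weight", "continuous", NULL, "kg", "recipient", TRUE),
    tribble_row("diagnosis", "categorical", DIAGNOSIS_LEVELS, "", "recipient", TRUE),
    tribble_row("diabetes", "indicator", NULL, "", "recipient", TRUE),
    tribble_row("hypertension", "indicator", NULL, "", "recipient", TRUE),
    tribble_row("infection_2wk", "indicator", NULL, "", "recipient", TRUE),
    tribble_row("antiarrhythmics", "indicator", NULL, "", "recipient", TRUE),
    tribble_row("amiodarone", "indicator", NULL, "", "recipient", TRUE),
    tribble_row("prior_transfusion", "indicator", NULL, "", "recipient", TRUE),
    tribble_row("prior_transplant", "indicator", NULL, "", "recipient", TRUE),
    tribble_row("prior_cardiac_surgery", "indicator", NULL, "", "recipient", TRUE),
    tribble_row("icu", "indicator", NULL, "", "recipient", TRUE),
    tribble_row("ventilator", "indicator", NULL, "", "recipient", TRUE),
    tribble_row("ecmo", "indicator", NULL, "", "recipient", TRUE),
    tribble_row("vad", "indicator", NULL, "", "recipient", TRUE),
    tribble_row("era", "categorical", ERA_LEVELS, "", "recipient", FALSE),
    tribble_row("spp", "continuous", NULL, "mmHg", "recipient", TRUE),
    tribble_row("pvr", "continuous", NULL, "Wood units", "recipient", TRUE),
    tribble_row("creatinine", "continuous", NULL, "umol/l", "recipient", TRUE),
    tribble_row("bilirubin", "continuous", NULL, "mg/dl", "recipient", TRUE),
    tribble_row("pra_gt10", "indicator", NULL, "", "recipient", TRUE),
    tribble_row("hladr_mismatch", "categorical", c("0", "1", "2"), "", "recipient", TRUE),
    tribble_row("recipient_bg", "categorical", BLOOD_GROUPS, "", "recipient", TRUE),
    tribble_row("donor_age", "continuous", NULL, "years", "donor", TRUE),
    tribble_row("donor_sex", "categorical", SEX_LEVELS, "", "donor", TRUE),
    tribble_row("donor_weight", "continuous", NULL, "kg", "donor", TRUE),
    tribble_row("ischemia_min", "continuous", NULL, "minutes", "donor", TRUE),
    tribble_row("codd_head_trauma", "indicator", NULL, "", "donor", TRUE),
    tribble_row("codd_cva", "indicator", NULL, "", "donor", TRUE),
    tribble_row("donor_bg", "categorical", BLOOD_GROUPS, "", "donor", TRUE),
    tribble_row("followup_years", "continuous", NULL, "years", "outcome", FALSE),
    tribble_row("death", "indicator", NULL, "", "outcome", FALSE)
  )
}

schema_var_names <- function(schema = ihtsa_schema(), covariates_only = FALSE) {
  nm <- schema$name
  if (covariates_only) nm <- setdiff(nm, c("followup_years", "death"))
  nm
}

#' Validate a cohort against the column dictionary
#'
#' Checks presence and typing of every schema column, admissible categorical
#' levels, non-negative follow-up, binary death indicator, and that the
#' protected columns (`followup_years`, `death`, `era`) carry no missing
#' values.
#'
#' @param cohort A cohort tibble/data frame.
#' @param schema Column dictionary, see [ihtsa_schema()].
#' @param allow_extra Keep (and ignore) columns not in the schema? Default
#'   `FALSE`: unknown columns are an error.
#' @return The cohort, invisibly, as a tibble (errors otherwise).
#' @export
validate_cohort <- function(cohort, schema = ihtsa_schema(), allow_extra = FALSE) {
  cohort <- as_tibble(cohort)
  missing_cols <- setdiff(schema$name, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "cohort is missing mandatory column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "ihtsa_schema_error")
  }
  extra <- setdiff(names(cohort), schema$name)
  if (length(extra) > 0 && !allow_extra) {
    abort(paste0(
      "unknown column(s): ", paste(extra, collapse = ", "),
      " (set allow_extra = TRUE to pass them through)"
    ), class = "ihtsa_schema_error")
  }
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    x <- cohort[[nm]]
    kind <- schema$kind[i]
    if (kind %in% c("continuous", "indicator")) {
      if (!is.numeric(x)) {
        abort(paste0("column ", nm, " must be numeric"),
          class = "ihtsa_parse_error"
        )
      }
      if (kind == "indicator" && !all(x[!is.na(x)] %in% c(0, 1))) {
        abort(paste0("indicator column ", nm, " contains values outside {0, 1}"),
          class = "ihtsa_parse_error"
        )
      }
    } else {
      levs <- schema$levels[[i]]
      bad <- setdiff(unique(as.character(x[!is.na(x)])), levs)
      if (length(bad) > 0) {
        abort(paste0(
          "column ", nm, " has unknown level(s): ",
          paste(bad, collapse = ", ")
        ), class = "ihtsa_parse_error")
      }
    }
    if (nm %in% PROTECTED_COLUMNS && anyNA(x)) {
      abort(paste0("protected column ", nm, " may not contain missing values"),
        class = "ihtsa_schema_error"
      )
    }
  }
  if (any(cohort$followup_years < 0)) {
    abort("followup_years must be >= 0", class = "ihtsa_parse_error")
  }
  age_cols <- c("recipient_age", "donor_age")
  for (nm in age_cols) {
    if (any(cohort[[nm]] <= 0, na.rm = TRUE)) {
      abort(paste0(nm, " must be > 0 when present"), class = "ihtsa_parse_error")
    }
  }
  invisible(cohort)
}

#' Read a transplant cohort from CSV
#'
#' Reads a cohort CSV (UTF-8, comma separated, `.` decimal mark) against the
#' column dictionary. Empty cells become NA (the missing flag); units are
#' taken as declared by the schema, no conversion is performed.
#'
#' @inheritParams validate_cohort
#' @param path Path to a CSV file.
#' @param name Cohort label stored in the `"cohort_name"` attribute.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, schema = ihtsa_schema(), allow_extra = FALSE,
                        name = basename(path)) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ihtsa_io_error")
  }
  hdr <- names(readr::read_csv(path,
    n_max = 0, show_col_types = FALSE,
    progress = FALSE
  ))
  present <- schema[schema$name %in% hdr, , drop = FALSE]
  col_types <- purrr::map(
    setNames(present$kind, present$name),
    ~ if (.x == "categorical") readr::col_character() else readr::col_double()
  )
  dat <- readr::read_csv(
    path,
    col_types = do.call(readr::cols, c(col_types, .default = readr::col_guess())),
    na = c("", "NA"), progress = FALSE, show_col_types = FALSE
  )
  prob <- readr::problems(dat)
  if (nrow(prob) > 0) {
    abort(paste0(
      "parse error at row ", prob$row[1], ", column ", prob$col[1],
      ": expected ", prob$expected[1], ", got ", prob$actual[1]
    ), class = "ihtsa_parse_error")
  }
  dat <- validate_cohort(dat, schema, allow_extra = allow_extra)
  attr(dat, "cohort_name") <- name
  dat
}

#' Write a transplant cohort to CSV
#'
#' Inverse of [read_cohort()]: missing cells are written as empty strings, so
#' read -> write round-trips cell-for-cell.
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' Randomly split a cohort into derivation and validation parts
#'
#' Draws a seeded random partition of the records into a derivation cohort
#' (DC) and an independent internal validation cohort (IVC), mirroring the
#' registry practice of holding out a fixed fraction for validation.
#'
#' @param cohort A cohort tibble.
#' @param fractions Numeric length-2 vector `(f_dc, f_ivc)` summing to 1,
#'   each in (0, 1).
#' @param seed Integer seed; identical seeds reproduce identical partitions.
#' @return A list with elements `dc` and `ivc`, both cohort tibbles. The DC
#'   receives `round(n * f_dc)` records, the IVC the remainder.
#' @export
#' @examples
#' co <- generate_cohort(generator_config(n = 100, seed = 1))$cohort
#' sp <- split_cohort(co, c(0.83, 0.17), seed = 7)
#' nrow(sp$dc) # 83
split_cohort <- function(cohort, fractions = c(0.83, 0.17), seed = 1) {
  if (length(fractions) != 2 || any(fractions <= 0) || any(fractions >= 1) ||
    abs(sum(fractions) - 1) > 1e-8) {
    abort("fractions must be two values in (0,1) summing to 1",
      class = "ihtsa_argument_error"
    )
  }
  n <- nrow(cohort)
  if (n == 0) abort("cohort is empty", class = "ihtsa_argument_error")
  n_dc <- round_half_up(n * fractions[1])
  idx <- with_seed(seed_stream(seed, "split"), sample.int(n))
  dc <- cohort[sort(idx[seq_len(n_dc)]), , drop = FALSE]
  ivc <- cohort[sort(idx[seq.int(n_dc + 1, length.out = n - n_dc)]), , drop = FALSE]
  attr(dc, "cohort_name") <- "dc"
  attr(ivc, "cohort_name") <- "ivc"
  list(dc = dc, ivc = ivc)
}

#' Half-IQR increment of a continuous variable
#'
#' The perturbation step used for continuous variables in counterfactual
#' hazard-ratio computation: half the interquartile range, rounded half-up to
#' the nearest integer in the variable's native unit. Quartiles use the
#' standard linear-interpolation (type 7) estimator. A zero increment (a
#' constant sample) is returned as 0 with attribute `degenerate = TRUE`; such
#' variables are excluded from hazard-ratio perturbation.
#'
#' @param values Numeric sample; NAs dropped; at least 4 non-missing values.
#' @param round_to_integer Round the increment half-up to an integer
#'   (default). Set `FALSE` for variables measured on sub-unit scales.
#' @return A single number, possibly with attribute `degenerate`.
#' @export
#' @examples
#' half_iqr_increment(c(88, 96, 106, 118, 132)) # creatinine-like
half_iqr_increment <- function(values, round_to_integer = TRUE) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    abort("all values missing", class = "ihtsa_argument_error")
  }
  if (length(values) < 4) {
    abort("need >= 4 non-missing values", class = "ihtsa_argument_error")
  }
  q <- unname(quantile(values, c(0.25, 0.75), type = 7))
  inc <- (q[2] - q[1]) / 2
  if (round_to_integer) inc <- round_half_up(inc)
  if (inc == 0) {
    attr(inc, "degenerate") <- TRUE
  }
  inc
}
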