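# Design-matrix construction: multi-level categoricals are dichotomized to
# k - 1 reference-coded indicator columns, continuous columns are standardized
# to zero mean / unit variance with statistics stored at fit time, and the
# derived recipient/donor weight and height ratios are appended. The stored
# statistics are re-applied verbatim to new data so fit-time and
# transform-time matrices agree exactly.

default_reference_levels <- function() {
  list(
    recipient_sex = "male",
    donor_sex = "male",
    diagnosis = "non_ischemic_cm",
    era = "1991-1995",
    hladr_mismatch = "0",
    recipient_bg = "AB",
    donor_bg = "A"
  )
}

# Derived body-size match features: recipient value divided by donor value.
# The standard column dictionary carries no donor height, so the height ratio
# is only available when a pass-through donor_height column is present.
add_ratio_columns <- function(cohort) {
  cohort$weight_ratio <- cohort$recipient_weight / cohort$donor_weight
  if (all(c("recipient_height", "donor_height") %in% names(cohort)) &&
    !anyNA(cohort$donor_height)) {
    cohort$height_ratio <- cohort$recipient_height / cohort$donor_height
  }
  cohort
}

#' Build a standardized design matrix from a complete cohort
#'
#' Encodes the model variables of a (post-imputation, complete) cohort as an
#' n x p numeric matrix: reference-coded 0/1 indicators for categorical
#' variables, standardized continuous columns, plus derived recipient/donor
#' weight and height ratios. Standardization statistics and half-IQR
#' increments are computed from the fitting cohort and stored in the returned
#' object so that [design_transform()] maps any new cohort into exactly the
#' same coordinates.
#'
#' @param cohort A complete cohort tibble (no missing values among the chosen
#'   variables).
#' @param variables Character vector of schema variable names to include.
#'   Defaults to all covariates.
#' @param reference_levels Named list mapping categorical variables to their
#'   dropped reference level; defaults via `default_reference_levels()`.
#' @param add_ratios Append the derived weight/height ratio columns
#'   (requires recipient and donor weight among `variables`).
#' @param schema Column dictionary.
#' @return An object of class `ihtsa_design` with elements `x` (the matrix),
#'   `column_names`, `column_kinds`, `centers`, `scales`, `increments`
#'   (half-IQR steps of continuous columns in native units), `variables`,
#'   `reference_levels`, `levels` (per categorical variable).
#' @export
build_design <- function(cohort, variables = NULL, reference_levels = NULL,
                         add_ratios = TRUE, schema = ihtsa_schema()) {
  variables <- variables %||% schema_var_names(schema, covariates_only = TRUE)
  refs <- utils::modifyList(default_reference_levels(), reference_levels %||% list())
  bad <- setdiff(variables, schema$name)
  if (length(bad) > 0) {
    abort(paste0("unknown variable(s): ", paste(bad, collapse = ", ")),
      class = "ihtsa_argument_error"
    )
  }
  sub <- cohort[, variables, drop = FALSE]
  if (anyNA(sub)) {
    abort("cohort must be complete (imputed) for all design variables",
      class = "ihtsa_argument_error"
    )
  }
  spec <- list(
    variables = variables,
    reference_levels = refs,
    add_ratios = add_ratios && all(c("recipient_weight", "donor_weight") %in% variables),
    schema = schema[schema$name %in% variables, , drop = FALSE]
  )
  raw <- design_raw(cohort, spec)
  centers <- vapply(seq_len(ncol(raw$x)), function(j) {
    if (raw$kinds[j] == "continuous") mean(raw$x[, j]) else 0
  }, numeric(1))
  scales <- vapply(seq_len(ncol(raw$x)), function(j) {
    if (raw$kinds[j] == "continuous") {
      s <- sd(raw$x[, j])
      if (s == 0) 1 else s
    } else {
      1
    }
  }, numeric(1))
  increments <- numeric(0)
  for (j in which(raw$kinds == "continuous")) {
    inc <- half_iqr_increment(raw$x[, j], round_to_integer = FALSE)
    increments[colnames(raw$x)[j]] <- as.numeric(inc)
  }
  design <- structure(
    list(
      column_names = colnames(raw$x),
      column_kinds = raw$kinds,
      centers = centers,
      scales = scales,
      increments = increments,
      variables = variables,
      reference_levels = refs[names(refs) %in% variables],
      levels = raw$levels,
      add_ratios = spec$add_ratios,
      schema = spec$schema
    ),
    class = "ihtsa_design"
  )
  design$x <- scale_design(raw$x, design)
  design
}

# Unstandardized encoding shared by fit and transform paths.
design_raw <- function(cohort, spec) {
  schema <- spec$schema
  cols <- list()
  kinds <- character(0)
  levels_map <- list()
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    kind <- schema$kind[i]
    x <- cohort[[nm]]
    if (kind == "continuous") {
      cols[[nm]] <- as.numeric(x)
      kinds[nm] <- "continuous"
    } else if (kind == "indicator") {
      cols[[nm]] <- as.numeric(x)
      kinds[nm] <- "indicator"
    } else {
      levs <- schema$levels[[i]]
      ref <- spec$reference_levels[[nm]] %||% levs[1]
      x <- as.character(x)
      unseen <- setdiff(unique(x), levs)
      if (length(unseen) > 0) {
        abort(paste0("unseen level(s) in ", nm, ": ", paste(unseen, collapse = ", ")),
          class = "ihtsa_transform_error"
        )
      }
      keep <- setdiff(levs, ref)
      levels_map[[nm]] <- list(levels = levs, reference = ref)
      for (lv in keep) {
        cname <- paste0(nm, "_", gsub("[^A-Za-z0-9]+", "_", lv))
        cols[[cname]] <- as.numeric(x == lv)
        kinds[cname] <- "indicator"
      }
    }
  }
  if (spec$add_ratios) {
    rat <- add_ratio_columns(cohort)
    cols[["weight_ratio"]] <- rat$weight_ratio
    kinds["weight_ratio"] <- "continuous"
    if ("height_ratio" %in% names(rat)) {
      cols[["height_ratio"]] <- rat$height_ratio
      kinds["height_ratio"] <- "continuous"
    }
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  list(x = x, kinds = kinds, levels = levels_map)
}

scale_design <- function(x, design) {
  sweep(sweep(x, 2, design$centers, "-"), 2, design$scales, "/")
}

#' Transform a cohort with fitted design statistics
#'
#' Applies a fitted [build_design()] encoding (same columns, same
#' standardization statistics) to new data. Encountering a categorical level
#' absent from the schema is a transform error.
#'
#' @param design An `ihtsa_design` object.
#' @param cohort A complete cohort tibble.
#' @return An n x p numeric matrix with the design's columns.
#' @export
design_transform <- function(design, cohort) {
  stopifnot(inherits(design, "ihtsa_design"))
  sub <- cohort[, design$variables, drop = FALSE]
  if (anyNA(sub)) {
    miss <- design$variables[vapply(sub, anyNA, logical(1))]
    abort(paste0(
      "missing value(s) in model variable(s): ",
      paste(miss, collapse = ", ")
    ), class = "ihtsa_prediction_error")
  }
  spec <- list(
    variables = design$variables,
    reference_levels = design$reference_levels,
    add_ratios = design$add_ratios,
    schema = design$schema
  )
  raw <- design_raw(cohort, spec)
  if (!identical(colnames(raw$x), design$column_names)) {
    abort("transform produced different columns than fit",
      class = "ihtsa_transform_error"
    )
  }
  scale_design(raw$x, design)
}

#' @export
print.ihtsa_design <- function(x, ...) {
  cat(
    "<ihtsa_design> ", length(x$column_names), " columns from ",
    length(x$variables), " variables (",
    sum(x$column_kinds == "continuous"), " continuous, ",
    sum(x$column_kinds == "indicator"), " indicator)\n",
    sep = ""
  )
  invisible(x)
}
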