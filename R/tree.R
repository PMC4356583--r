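# CART summary of model-predicted median survival. The response is the
# model's predicted median survival (optionally era-adjusted to the latest
# era); the tree is grown by greedy binary recursive partitioning of the
# within-node sum of squares (rpart, anova method, no surrogate or competitor
# splits), pruned by weakest-link cost-complexity, and summarized by the
# proportion of root-node variability each variable's splits account for.

#' Fit a regression tree to predicted median survival
#'
#' @param features Data frame of recipient/donor covariates (character
#'   columns are treated as factors; must be complete).
#' @param target Numeric response per record, typically
#'   `predicted_median_survival(model, cohort, era_adjust = TRUE)$median_years`.
#' @param min_leaf Minimum records per leaf (default 50). `min_leaf >= n`
#'   yields a single-leaf tree.
#' @param cc_alpha Cost-complexity parameter used while growing (default 0:
#'   grow fully, prune later with [prune_tree()]).
#' @return An `ihtsa_tree`: wraps the `rpart` fit plus `n`, `root_sse`.
#' @export
fit_tree <- function(features, target, min_leaf = 50, cc_alpha = 0) {
  if (any(!is.finite(target))) {
    abort("nonfinite target", class = "ihtsa_argument_error")
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  features[] <- lapply(features, function(x) {
    if (is.character(x)) factor(x) else x
  })
  if (anyNA(features)) {
    abort("features must be complete", class = "ihtsa_argument_error")
  }
  dat <- cbind(.target = target, features)
  fit <- rpart::rpart(
    .target ~ .,
    data = dat, method = "anova",
    control = rpart::rpart.control(
      cp = cc_alpha, minbucket = min_leaf, minsplit = 2 * min_leaf,
      xval = 0, maxsurrogate = 0, maxcompete = 0, usesurrogate = 0
    )
  )
  structure(
    list(
      rpart = fit, n = length(target),
      root_sse = sum((target - mean(target))^2),
      min_leaf = min_leaf
    ),
    class = "ihtsa_tree"
  )
}

#' Weakest-link cost-complexity pruning
#'
#' Collapses subtrees whose per-split error reduction, normalized by the
#' root-node total sum of squares, falls below `cc_alpha`. `cc_alpha = 0`
#' returns the tree unchanged.
#'
#' @param tree An `ihtsa_tree`.
#' @param cc_alpha Complexity parameter (>= 0; registry-scale figures use
#'   0.0035).
#' @return The pruned `ihtsa_tree`.
#' @export
prune_tree <- function(tree, cc_alpha = 0.0035) {
  if (cc_alpha < 0) abort("cc_alpha must be >= 0", class = "ihtsa_argument_error")
  if (cc_alpha == 0) {
    return(tree)
  }
  tree$rpart <- rpart::prune(tree$rpart, cp = cc_alpha)
  tree
}

# Internal-node table: node number, split variable, SSE reduction.
tree_split_table <- function(tree) {
  fr <- tree$rpart$frame
  node_ids <- as.integer(rownames(fr))
  internal <- which(fr$var != "<leaf>")
  if (length(internal) == 0) {
    return(tibble(
      node = integer(), variable = character(),
      sse_reduction = numeric()
    ))
  }
  purrr::map_dfr(internal, function(i) {
    id <- node_ids[i]
    kids <- match(c(2L * id, 2L * id + 1L), node_ids)
    tibble(
      node = id,
      variable = as.character(fr$var[i]),
      sse_reduction = fr$dev[i] - fr$dev[kids[1]] - fr$dev[kids[2]]
    )
  })
}

#' Variable importance as proportion of variability
#'
#' For each variable, the sum of within-node sum-of-squares reductions over
#' the primary splits on that variable, divided by the root-node total sum
#' of squares, so the values read as fractions of explained variability and
#' sum to the tree's overall explained-variance fraction (<= 1).
#'
#' @param tree An `ihtsa_tree`.
#' @return A tibble with `variable` and `importance`, in decreasing order
#'   (empty for a root-only tree).
#' @export
tree_importance <- function(tree) {
  splits <- tree_split_table(tree)
  if (nrow(splits) == 0) {
    return(tibble(variable = character(), importance = numeric()))
  }
  splits |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(
      importance = sum(.data$sse_reduction) / tree$root_sse,
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Leaf summary of a fitted tree
#'
#' @param tree An `ihtsa_tree`.
#' @param target Optional training targets to recover per-leaf SD (uses the
#'   rpart frame mean and n regardless).
#' @return A tibble: `leaf` (node number), `n`, `predicted_median`, `sd`
#'   (NA without `target`).
#' @export
tree_leaves <- function(tree, target = NULL) {
  fr <- tree$rpart$frame
  node_ids <- as.integer(rownames(fr))
  leaves <- which(fr$var == "<leaf>")
  out <- tibble(
    leaf = node_ids[leaves],
    n = fr$n[leaves],
    predicted_median = fr$yval[leaves],
    sd = sqrt(fr$dev[leaves] / pmax(fr$n[leaves] - 1, 1))
  )
  out
}

# Route records of a data frame to leaf node numbers by walking the frame /
# splits tables (handles continuous and categorical primary splits; no
# surrogates are fitted).
route_to_leaves <- function(tree, features) {
  fit <- tree$rpart
  fr <- fit$frame
  node_ids <- as.integer(rownames(fr))
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  features[] <- lapply(features, function(x) if (is.character(x)) factor(x) else x)
  xlev <- attr(fit, "xlevels")
  n <- nrow(features)
  out <- integer(n)
  splits <- fit$splits
  csplit <- fit$csplit
  # primary split row per internal node, in frame order
  internal <- which(fr$var != "<leaf>")
  split_row <- integer(nrow(fr))
  if (length(internal) > 0) split_row[internal] <- seq_along(internal)
  for (i in seq_len(n)) {
    node_pos <- 1L
    while (fr$var[node_pos] != "<leaf>") {
      v <- as.character(fr$var[node_pos])
      srow <- splits[split_row[node_pos], , drop = TRUE]
      val <- features[[v]][i]
      ncat <- srow[["ncat"]]
      go_left <- if (abs(ncat) == 1) {
        if (ncat == -1) val < srow[["index"]] else val >= srow[["index"]]
      } else {
        lev <- as.integer(factor(as.character(val), levels = xlev[[v]]))
        csplit[as.integer(srow[["index"]]), lev] == 1L
      }
      id <- node_ids[node_pos]
      child <- if (go_left) 2L * id else 2L * id + 1L
      node_pos <- match(child, node_ids)
    }
    out[i] <- node_ids[node_pos]
  }
  out
}

#' Validate tree leaves on observed survival
#'
#' Routes derivation- and validation-cohort records to the tree's leaves,
#' estimates the observed Kaplan-Meier curve per leaf per cohort, and tests
#' DC vs IVC within each leaf by the log-rank test. A leaf empty in either
#' cohort is skipped with a warning.
#'
#' @param tree An `ihtsa_tree`.
#' @param cohort_dc,cohort_ivc Cohort tibbles carrying the tree's feature
#'   columns plus `followup_years` and `death`.
#' @param leaves Optional leaf node numbers (default: all leaves).
#' @return A list: `km` (tibble of per-leaf, per-cohort KM curves),
#'   `log_rank` (tibble with `leaf`, `chi2`, `p_value`), `assignment`
#'   (per-record leaf ids).
#' @export
validate_leaves <- function(tree, cohort_dc, cohort_ivc, leaves = NULL) {
  all_leaves <- tree_leaves(tree)$leaf
  leaves <- leaves %||% all_leaves
  feat_names <- setdiff(
    all.vars(tree$rpart$terms), ".target"
  )
  leaf_dc <- route_to_leaves(tree, cohort_dc[, feat_names, drop = FALSE])
  leaf_ivc <- route_to_leaves(tree, cohort_ivc[, feat_names, drop = FALSE])
  km <- list()
  lr <- list()
  for (lf in leaves) {
    in_dc <- leaf_dc == lf
    in_ivc <- leaf_ivc == lf
    if (sum(in_dc) == 0 || sum(in_ivc) == 0) {
      warn(paste0("leaf ", lf, " empty in one cohort; skipped"))
      next
    }
    km[[length(km) + 1]] <- dplyr::bind_rows(
      dplyr::mutate(
        kaplan_meier(
          cohort_dc$followup_years[in_dc],
          cohort_dc$death[in_dc]
        ),
        leaf = lf, cohort = "dc"
      ),
      dplyr::mutate(
        kaplan_meier(
          cohort_ivc$followup_years[in_ivc],
          cohort_ivc$death[in_ivc]
        ),
        leaf = lf, cohort = "ivc"
      )
    )
    lrt <- tryCatch(
      log_rank(
        cohort_dc$followup_years[in_dc], cohort_dc$death[in_dc],
        cohort_ivc$followup_years[in_ivc], cohort_ivc$death[in_ivc]
      ),
      error = function(e) list(chi2 = NA_real_, p_value = NA_real_)
    )
    lr[[length(lr) + 1]] <- tibble(
      leaf = lf, chi2 = lrt$chi2, p_value = lrt$p_value
    )
  }
  list(
    km = if (length(km)) dplyr::bind_rows(km) else tibble(),
    log_rank = if (length(lr)) dplyr::bind_rows(lr) else tibble(),
    assignment = list(dc = leaf_dc, ivc = leaf_ivc)
  )
}

#' @export
print.ihtsa_tree <- function(x, ...) {
  lv <- tree_leaves(x)
  cat(
    "<ihtsa_tree> ", nrow(lv), " leaves over ", x$n, " records; ",
    "explained variance ",
    sprintf("%.1f%%", 100 * sum(tree_importance(x)$importance)), "\n",
    sep = ""
  )
  invisible(x)
}
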