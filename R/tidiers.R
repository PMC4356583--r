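# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @rdname ihtsa_tidiers
#' @param x An `ihtsa_curves` object.
#' @param ... Unused.
#' @method tidy ihtsa_curves
#' @export
tidy.ihtsa_curves <- function(x, ...) {
  K <- ncol(x$hazard)
  n <- nrow(x$hazard)
  tibble(
    record = rep(seq_len(n), times = K),
    interval = rep(seq_len(K), each = n),
    t_start = rep(x$boundaries[seq_len(K)], each = n),
    t_end = rep(x$boundaries[seq_len(K) + 1], each = n),
    hazard = as.vector(x$hazard),
    survival = as.vector(x$survival)
  ) |>
    dplyr::arrange(.data$record, .data$interval)
}

#' Tidiers for fitted ihtsa objects
#'
#' `tidy()` returns one row per component (interval, variable, leaf...);
#' `glance()` returns a one-row model summary.
#'
#' @name ihtsa_tidiers
NULL

#' @rdname ihtsa_tidiers
#' @method tidy ihtsa_ensemble
#' @export
tidy.ihtsa_ensemble <- function(x, ...) {
  b <- x$grid$boundaries
  K <- x$grid$K
  tibble(
    interval = seq_len(K),
    t_start = b[seq_len(K)],
    t_end = b[seq_len(K) + 1]
  )
}

#' @rdname ihtsa_tidiers
#' @method glance ihtsa_ensemble
#' @export
glance.ihtsa_ensemble <- function(x, ...) {
  tibble(
    members = length(x$members),
    inputs = x$members[[1]]$input_dim,
    hidden = x$members[[1]]$hidden,
    intervals = x$grid$K,
    aggregation = x$aggregation
  )
}

#' @rdname ihtsa_tidiers
#' @method tidy ihtsa_hr_estimate
#' @export
tidy.ihtsa_hr_estimate <- function(x, ...) {
  as_tibble(unclass(x)[c("variable", "increment", "time", "hr", "lower", "upper")])
}

#' @rdname ihtsa_tidiers
#' @method glance ihtsa_concordance
#' @export
glance.ihtsa_concordance <- function(x, ...) {
  tibble(
    c_index = x$c, comparable_pairs = x$comparable_pairs,
    concordant = x$concordant, discordant = x$discordant, tied = x$tied,
    ci_lower = x$ci[["lower"]], ci_upper = x$ci[["upper"]]
  )
}

#' @rdname ihtsa_tidiers
#' @method glance ihtsa_roc
#' @export
glance.ihtsa_roc <- function(x, ...) {
  tibble(
    auc = x$auc, se = sqrt(x$variance), n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @rdname ihtsa_tidiers
#' @method tidy ihtsa_ranking
#' @export
tidy.ihtsa_ranking <- function(x, ...) {
  tibble(
    removal = seq_along(x$elimination_order),
    variable = x$elimination_order,
    c_after_removal = x$c_trajectory[-1]
  )
}

#' @rdname ihtsa_tidiers
#' @method tidy ihtsa_tree
#' @export
tidy.ihtsa_tree <- function(x, ...) {
  tree_importance(x)
}

#' @rdname ihtsa_tidiers
#' @method glance ihtsa_tree
#' @export
glance.ihtsa_tree <- function(x, ...) {
  lv <- tree_leaves(x)
  tibble(
    leaves = nrow(lv), n = x$n,
    explained_variance = sum(tree_importance(x)$importance)
  )
}

#' Plot predicted survival curves
#'
#' Step/linear survival curves for each record of an `ihtsa_curves` object
#' (sampled down to at most `max_curves` for legibility).
#'
#' @param object An `ihtsa_curves`.
#' @param max_curves Cap on the number of plotted records (default 50).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ihtsa_curves
#' @export
autoplot.ihtsa_curves <- function(object, max_curves = 50, ...) {
  df <- tidy.ihtsa_curves(object)
  ids <- unique(df$record)
  if (length(ids) > max_curves) {
    ids <- ids[seq(1, length(ids), length.out = max_curves)]
    df <- df[df$record %in% ids, ]
  }
  anchor <- df[df$interval == 1, ]
  anchor$t_end <- anchor$t_start
  anchor$survival <- 1
  df <- rbind(anchor, df)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$t_end, y = .data$survival,
    group = .data$record
  )) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "Years after transplant", y = "Predicted survival") +
    ggplot2::ylim(0, 1)
}

#' Plot time-dependent hazard ratios
#'
#' Point estimates with bootstrap confidence bars at the reporting times.
#'
#' @param object An `ihtsa_hr_estimate` from [bootstrap_hr_ci()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ihtsa_hr_estimate
#' @export
autoplot.ihtsa_hr_estimate <- function(object, ...) {
  df <- tidy.ihtsa_hr_estimate(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$hr)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$lower,
      ymax = .data$upper
    )) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Years after transplant",
      y = paste0("Hazard ratio (", df$variable[1], ")")
    )
}

#' Plot a ranking trajectory
#'
#' Cross-validated C-index against the number of variables remaining.
#'
#' @param object An `ihtsa_ranking`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ihtsa_ranking
#' @export
autoplot.ihtsa_ranking <- function(object, ...) {
  n_total <- length(object$variables)
  df <- tibble(
    n_variables = n_total - (seq_along(object$c_trajectory) - 1),
    c_index = object$c_trajectory
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_variables, y = .data$c_index)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Variables in model", y = "CV C-index")
}

#' Plot per-policy allocation summaries
#'
#' @param object An `ihtsa_allocation_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ihtsa_allocation_run
#' @export
autoplot.ihtsa_allocation_run <- function(object, ...) {
  ggplot2::ggplot(
    object$summary,
    ggplot2::aes(x = .data$policy, y = .data$transplants)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Transplants performed")
}
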