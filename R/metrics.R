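# Discrimination and calibration metrics with the exact pair / grouping
# conventions used throughout the package: Harrell's C (pairs usable iff the
# shorter observed time is an event; score ties count 1/2), Somers'-D
# comparison of two concordance indices by paired jackknife, Mann-Whitney
# AUROC with DeLong structural-component variance, Hosmer-Lemeshow deciles,
# and logistic recalibration. Kaplan-Meier and the log-rank test are
# delegated to the survival package.

# Per-subject comparable/concordant/tied pair counts (each pair counted once
# per member), vectorized over the partner index.
concordance_counts <- function(scores, times, events) {
  n <- length(scores)
  comp_i <- conc_i <- tied_i <- numeric(n)
  for (i in seq_len(n)) {
    # pairs (i, j): usable iff the member with the shorter time has an event
    shorter_i <- times[i] < times[j_all <- seq_len(n)] & events[i] == 1
    shorter_j <- times < times[i] & events == 1
    usable <- shorter_i | shorter_j
    usable[i] <- FALSE
    # concordant when the longer-surviving member carries the higher score
    longer_score <- ifelse(shorter_i, scores, scores[i])
    shorter_score <- ifelse(shorter_i, scores[i], scores)
    conc <- usable & (longer_score > shorter_score)
    tie <- usable & (longer_score == shorter_score)
    comp_i[i] <- sum(usable)
    conc_i[i] <- sum(conc)
    tied_i[i] <- sum(tie)
  }
  list(comp = comp_i, conc = conc_i, tied = tied_i)
}

#' Harrell's concordance index
#'
#' Fraction of usable subject pairs in which the subject with the longer
#' observed survival carries the better (higher) predicted score. A pair is
#' usable iff the member with the shorter observed time died; score ties
#' count 1/2. The confidence interval uses the Noether-type asymptotic
#' variance `c(1-c)/n_pairs`.
#'
#' @param scores Numeric scores, higher = longer predicted survival.
#' @param times Observed follow-up times.
#' @param events 0/1 event indicators.
#' @param level Confidence level (default 0.95).
#' @return An `ihtsa_concordance` list: `c`, `comparable_pairs`,
#'   `concordant`, `discordant`, `tied`, `ci` (lower/upper), `level`.
#' @export
harrell_c <- function(scores, times, events, level = 0.95) {
  stopifnot(length(scores) == length(times), length(times) == length(events))
  if (sum(events) == 0) {
    abort("need at least one event", class = "ihtsa_argument_error")
  }
  # each usable pair counted once, anchored at its (event) shorter member
  comparable <- concordant <- tied <- 0
  for (i in which(events == 1)) {
    longer <- times > times[i]
    comparable <- comparable + sum(longer)
    concordant <- concordant + sum(scores[longer] > scores[i])
    tied <- tied + sum(scores[longer] == scores[i])
  }
  if (comparable == 0) {
    abort("no comparable pairs", class = "ihtsa_argument_error")
  }
  cval <- (concordant + 0.5 * tied) / comparable
  se <- sqrt(cval * (1 - cval) / comparable)
  z <- qnorm(1 - (1 - level) / 2)
  structure(
    list(
      c = cval, comparable_pairs = comparable,
      concordant = concordant, discordant = comparable - concordant - tied,
      tied = tied,
      ci = c(lower = max(0, cval - z * se), upper = min(1, cval + z * se)),
      level = level
    ),
    class = "ihtsa_concordance"
  )
}

#' @export
print.ihtsa_concordance <- function(x, ...) {
  cat(sprintf(
    "Harrell's C = %.4f (%d%% CI %.4f-%.4f), %s comparable pairs\n",
    x$c, round(100 * x$level), x$ci[1], x$ci[2],
    format(x$comparable_pairs, big.mark = ",")
  ))
  invisible(x)
}

#' Compare two concordance indices via Somers' D
#'
#' Paired comparison of two score sets on the same cohort through
#' `D = 2C - 1`, with the variance of the difference estimated by the
#' leave-one-out jackknife of the paired D estimates; two-sided normal
#' p-value. Identical score vectors give p = 1.
#'
#' @param scores_a,scores_b Two score vectors on the same subjects.
#' @inheritParams harrell_c
#' @return A list: `d_a`, `d_b`, `difference`, `se`, `z`, `p_value`.
#' @export
compare_c <- function(scores_a, scores_b, times, events) {
  stopifnot(length(scores_a) == length(scores_b))
  if (isTRUE(all.equal(as.numeric(scores_a), as.numeric(scores_b)))) {
    ca <- harrell_c(scores_a, times, events)$c
    return(list(
      d_a = 2 * ca - 1, d_b = 2 * ca - 1, difference = 0,
      se = 0, z = 0, p_value = 1
    ))
  }
  n <- length(times)
  cc_a <- concordance_counts(scores_a, times, events)
  cc_b <- concordance_counts(scores_b, times, events)
  d_of <- function(conc, tied, comp) {
    2 * ((conc + 0.5 * tied) / comp) - 1
  }
  tot <- function(cc) {
    list(comp = sum(cc$comp) / 2, conc = sum(cc$conc) / 2, tied = sum(cc$tied) / 2)
  }
  ta <- tot(cc_a)
  tb <- tot(cc_b)
  d_a <- d_of(ta$conc, ta$tied, ta$comp)
  d_b <- d_of(tb$conc, tb$tied, tb$comp)
  # leave-one-out: pairs involving subject i drop out
  theta <- vapply(seq_len(n), function(i) {
    da_i <- d_of(
      ta$conc - cc_a$conc[i], ta$tied - cc_a$tied[i],
      ta$comp - cc_a$comp[i]
    )
    db_i <- d_of(
      tb$conc - cc_b$conc[i], tb$tied - cc_b$tied[i],
      tb$comp - cc_b$comp[i]
    )
    da_i - db_i
  }, numeric(1))
  jack_var <- (n - 1) / n * sum((theta - mean(theta))^2)
  se <- sqrt(max(jack_var, 0))
  diff <- d_a - d_b
  z <- if (se == 0) 0 else diff / se
  list(
    d_a = d_a, d_b = d_b, difference = diff, se = se, z = z,
    p_value = if (se == 0) 1 else 2 * pnorm(-abs(z))
  )
}

# DeLong structural components: V10 (one per case), V01 (one per control).
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(
    auc = mean(psi),
    v10 = rowMeans(psi),
    v01 = colMeans(psi),
    n_pos = length(pos), n_neg = length(neg)
  )
}

#' AUROC for one-year mortality with DeLong variance
#'
#' Mann-Whitney area under the ROC curve with tie correction and the DeLong
#' structural-component variance. Use [one_year_labels()] to derive the 0/1
#' labels from follow-up (subjects censored before the horizon without death
#' are excluded).
#'
#' @param scores Risk scores, higher = more likely to die.
#' @param labels 0/1 outcome labels; both classes must be present.
#' @return An `ihtsa_roc` list: `auc`, `variance`, `n_pos`, `n_neg`, plus
#'   the structural components used by [delong_test()].
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) {
    abort("both outcome classes must be present", class = "ihtsa_argument_error")
  }
  comp <- delong_components(scores, labels)
  variance <- var(comp$v10) / comp$n_pos + var(comp$v01) / comp$n_neg
  structure(
    list(
      auc = comp$auc, variance = variance,
      n_pos = comp$n_pos, n_neg = comp$n_neg,
      v10 = comp$v10, v01 = comp$v01
    ),
    class = "ihtsa_roc"
  )
}

#' @export
print.ihtsa_roc <- function(x, ...) {
  cat(sprintf(
    "AUROC = %.4f (DeLong SE %.4f), %d cases / %d controls\n",
    x$auc, sqrt(x$variance), x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' One-year mortality labels from follow-up
#'
#' Death within the horizon is 1; survival beyond the horizon (dead or
#' alive) is 0; records censored alive before the horizon carry no label and
#' are excluded.
#'
#' @param times,events Follow-up years and 0/1 death indicators.
#' @param horizon Label horizon in years (default 1).
#' @return A list: `labels` (0/1), `keep` (logical index into the input),
#'   `n_excluded`.
#' @export
one_year_labels <- function(times, events, horizon = 1) {
  died_by <- events == 1 & times <= horizon
  alive_at <- times >= horizon & !(events == 1 & times <= horizon)
  keep <- died_by | alive_at
  list(
    labels = as.numeric(died_by[keep]),
    keep = keep,
    n_excluded = sum(!keep)
  )
}

#' DeLong test comparing two correlated AUROCs
#'
#' Two-sided z-test on the difference of two areas computed on the same
#' subjects, using the paired DeLong covariance of the structural
#' components. Identical score vectors give p = 1.
#'
#' @param roc_a,roc_b [auroc()] results computed on the same subjects (in
#'   the same order).
#' @return A list: `auc_a`, `auc_b`, `difference`, `se`, `z`, `p_value`.
#' @export
delong_test <- function(roc_a, roc_b) {
  stopifnot(inherits(roc_a, "ihtsa_roc"), inherits(roc_b, "ihtsa_roc"))
  if (roc_a$n_pos != roc_b$n_pos || roc_a$n_neg != roc_b$n_neg) {
    abort("ROC results are not paired", class = "ihtsa_argument_error")
  }
  cov10 <- stats::cov(roc_a$v10, roc_b$v10)
  cov01 <- stats::cov(roc_a$v01, roc_b$v01)
  var_diff <- roc_a$variance + roc_b$variance -
    2 * (cov10 / roc_a$n_pos + cov01 / roc_a$n_neg)
  diff <- roc_a$auc - roc_b$auc
  if (var_diff <= 0 || (diff == 0 && var_diff < 1e-16)) {
    return(list(
      auc_a = roc_a$auc, auc_b = roc_b$auc, difference = diff,
      se = sqrt(max(var_diff, 0)), z = 0, p_value = 1
    ))
  }
  se <- sqrt(var_diff)
  z <- diff / se
  list(
    auc_a = roc_a$auc, auc_b = roc_b$auc, difference = diff,
    se = se, z = z, p_value = 2 * pnorm(-abs(z))
  )
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups subjects into `g` equal-count groups of predicted risk (ties to
#' the lower group), then compares observed and expected event counts:
#' `chi2 = sum (O - E)^2 / (E (1 - E / n_g))` on `g - 2` degrees of freedom.
#' Groups with zero expected events are merged into their neighbor with a
#' warning and the degrees of freedom adjusted.
#'
#' @param pred Predicted event probabilities in `[0, 1]`.
#' @param outcomes 0/1 observed events.
#' @param g Number of groups (default 10).
#' @param external Were the predictions produced without fitting to these
#'   outcomes (external validation)? Then the null distribution has `g`
#'   degrees of freedom rather than the in-sample `g - 2`; using `g - 2` on
#'   external data inflates the type-I error (to roughly 0.10 at g = 10).
#'   Default `FALSE` (the classical in-sample convention).
#' @return A list: `chi2`, `dof`, `p_value`, `table` (per-group tibble).
#' @export
hosmer_lemeshow <- function(pred, outcomes, g = 10, external = FALSE) {
  stopifnot(length(pred) == length(outcomes))
  if (any(pred < 0 | pred > 1)) {
    abort("predictions must be in [0,1]", class = "ihtsa_argument_error")
  }
  n <- length(pred)
  if (n < 5 * g) {
    abort("need n >= 5 g observations", class = "ihtsa_argument_error")
  }
  if (g - 2 < 1) {
    abort("g must be >= 3 for a testable statistic", class = "ihtsa_argument_error")
  }
  brks <- unique(quantile(pred, probs = seq(0, 1, length.out = g + 1), type = 7))
  grp <- cut(pred, breaks = brks, include.lowest = TRUE, labels = FALSE)
  tab <- tibble(pred = pred, y = outcomes, grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(
      n = dplyr::n(), observed = sum(.data$y), expected = sum(.data$pred),
      .groups = "drop"
    )
  # merge zero-expectation groups into the neighbor above
  merged <- FALSE
  while (any(tab$expected == 0 | tab$expected == tab$n) && nrow(tab) > 3) {
    i <- which(tab$expected == 0 | tab$expected == tab$n)[1]
    j <- if (i == nrow(tab)) i - 1 else i + 1
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$observed[j] <- tab$observed[j] + tab$observed[i]
    tab$expected[j] <- tab$expected[j] + tab$expected[i]
    tab <- tab[-i, ]
    merged <- TRUE
  }
  if (merged) {
    warn("Hosmer-Lemeshow groups merged due to degenerate expected counts")
  }
  g_eff <- nrow(tab)
  chi2 <- sum((tab$observed - tab$expected)^2 /
    (tab$expected * (1 - tab$expected / tab$n)))
  dof <- if (external) g_eff else g_eff - 2
  list(
    chi2 = chi2, dof = dof,
    p_value = pchisq(chi2, df = dof, lower.tail = FALSE),
    table = tab
  )
}

#' Logistic recalibration of predicted probabilities
#'
#' Fits `outcome ~ logit(pred)`; perfect calibration gives intercept 0 and
#' slope 1. Complete separation (or a degenerate constant predictor) is
#' flagged; separation falls back to a ridge-penalized Newton fit.
#'
#' @param pred Predicted probabilities in (0, 1).
#' @param outcomes 0/1 events, both classes present.
#' @return A list: `intercept`, `slope`, `separation` (logical flag).
#' @export
recalibrate_logistic <- function(pred, outcomes) {
  if (length(unique(outcomes)) < 2) {
    abort("both outcome classes must be present", class = "ihtsa_argument_error")
  }
  if (length(unique(pred)) < 2) {
    abort("degenerate predictor: pred is constant", class = "ihtsa_argument_error")
  }
  lp <- qlogis(pmin(pmax(pred, 1e-12), 1 - 1e-12))
  fit <- suppressWarnings(glm(outcomes ~ lp, family = binomial()))
  separated <- !fit$converged || any(abs(coef(fit)) > 20)
  if (separated) {
    # small-ridge Newton fallback keeps the estimate finite
    co <- ridge_logistic(cbind(1, lp), outcomes, lambda = 1e-4)
    return(list(intercept = co[1], slope = co[2], separation = TRUE))
  }
  list(
    intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
    separation = FALSE
  )
}

ridge_logistic <- function(X, y, lambda = 1e-4, iter = 50) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    H <- crossprod(X, X * W) + diag(lambda, ncol(X))
    g <- crossprod(X, y - mu) - lambda * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  drop(beta)
}

#' Kaplan-Meier estimate with Greenwood confidence bands
#'
#' Product-limit estimate via `survival::survfit`, returned as a tidy step
#' function with the Greenwood standard error and plain-scale confidence
#' band; `failure = 1 - survival`.
#'
#' @param times,events Follow-up times (>= 0) and 0/1 event indicators.
#' @param level Confidence level (default 0.95).
#' @return A tibble: `time`, `n_risk`, `n_event`, `survival`, `failure`,
#'   `std_err`, `lower`, `upper`.
#' @export
kaplan_meier <- function(times, events, level = 0.95) {
  if (any(times < 0)) abort("negative times", class = "ihtsa_argument_error")
  fit <- survival::survfit(
    survival::Surv(times, events) ~ 1,
    conf.type = "plain", conf.int = level
  )
  tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    survival = fit$surv, failure = 1 - fit$surv,
    std_err = fit$surv * fit$std.err,
    lower = fit$lower, upper = fit$upper
  )
}

#' Two-group log-rank test
#'
#' Standard 1-dof log-rank statistic via `survival::survdiff`.
#'
#' @param times_a,events_a,times_b,events_b Follow-up and 0/1 events of the
#'   two groups.
#' @return A list: `chi2`, `dof`, `p_value`.
#' @export
log_rank <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0 || length(times_b) == 0) {
    abort("both groups must be nonempty", class = "ihtsa_argument_error")
  }
  if (sum(events_a) + sum(events_b) == 0) {
    abort("no events in either group", class = "ihtsa_argument_error")
  }
  grp <- c(rep(0, length(times_a)), rep(1, length(times_b)))
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  sd <- survival::survdiff(survival::Surv(times, events) ~ grp)
  list(
    chi2 = sd$chisq, dof = 1,
    p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  )
}
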