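# Discrete time grid and the discrete-time likelihood expansion. Follow-up
# is partitioned into K right-open intervals [b_{k-1}, b_k); the conditional
# hazard h_k is the probability of death in interval k given survival to its
# start. A record dying in interval k contributes Bernoulli targets
# (0,...,0,1) over intervals 1..k; a record censored inside interval k
# contributes (0,...,0) over intervals 1..k-1 only (the partial interval
# yields no target).

#' Build a time grid from observed follow-up
#'
#' Places the K-1 interior boundaries at the equal-probability (type 7)
#' quantiles of the observed follow-up times, prepends 0 and appends the
#' maximum follow-up, so interval at-risk counts are balanced. Duplicate
#' boundaries (heavily tied follow-up) are merged with a warning and K
#' reduced.
#'
#' @param cohort A cohort tibble (uses `followup_years`), or a numeric vector
#'   of follow-up times.
#' @param K Number of intervals (default 25).
#' @return An object of class `ihtsa_time_grid`: list with `boundaries`
#'   (length K+1, starting at 0) and `K`.
#' @export
#' @examples
#' build_time_grid(1:100, K = 4)$boundaries
build_time_grid <- function(cohort, K = 25) {
  times <- if (is.data.frame(cohort)) cohort$followup_years else as.numeric(cohort)
  if (K < 1) abort("K must be >= 1", class = "ihtsa_argument_error")
  if (any(times < 0)) abort("negative follow-up", class = "ihtsa_argument_error")
  if (K == 1) {
    b <- c(0, max(times))
  } else {
    inner <- quantile(times, probs = seq_len(K - 1) / K, type = 7, names = FALSE)
    b <- c(0, inner, max(times))
  }
  b <- unique(b)
  if (length(b) < K + 1) {
    warn(paste0(
      "duplicate grid boundaries merged: K reduced from ", K,
      " to ", length(b) - 1
    ))
  }
  if (length(b) < 2) {
    # all follow-up times equal (and zero): single degenerate interval
    b <- c(0, max(times, 1e-8))
  }
  structure(list(boundaries = b, K = length(b) - 1), class = "ihtsa_time_grid")
}

# Index of the interval containing time t under the right-open convention,
# with the final interval absorbing the tail (closed on the right).
interval_index <- function(grid, t) {
  k <- findInterval(t, grid$boundaries, left.open = FALSE)
  pmin(pmax(k, 1L), grid$K)
}

#' Discrete-time targets for a cohort on a grid
#'
#' Expands each record into its at-risk interval prefix and event interval:
#' death inside interval k gives at-risk `{1..k}` with the event in k;
#' censoring inside interval k gives at-risk `{1..k-1}` and no event.
#'
#' @param cohort A cohort tibble with `followup_years` and `death`.
#' @param grid An [build_time_grid()] object.
#' @return A list with `at_risk` (n x K 0/1 matrix, prefix structure),
#'   `event` (n x K 0/1 matrix; row sums <= 1) and `grid`.
#' @export
make_targets <- function(cohort, grid) {
  t <- cohort$followup_years
  d <- cohort$death
  n <- length(t)
  K <- grid$K
  k_t <- interval_index(grid, t)
  # censored records stop being at risk at the start of their partial
  # interval; censoring exactly on a boundary (incl. the grid horizon) means
  # the preceding interval was fully survived
  raw <- findInterval(t, grid$boundaries, left.open = FALSE)
  n_at_risk <- ifelse(d == 1, k_t, pmin(raw - 1L, K))
  at_risk <- matrix(0, n, K)
  event <- matrix(0, n, K)
  col <- matrix(rep(seq_len(K), each = n), n, K)
  at_risk[col <= n_at_risk] <- 1
  event[cbind(which(d == 1), k_t[d == 1])] <- 1
  list(at_risk = at_risk, event = event, grid = grid)
}
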