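# Discrimination and calibration metrics against brute-force oracles,
# closed-form cases and independent implementations.

test_that("Harrell's C matches hand cases and the brute-force oracle", {
  # perfect ordering with all events
  expect_equal(harrell_c(1:10, 1:10, rep(1, 10))$c, 1)
  # constant scores -> 0.5
  expect_equal(harrell_c(rep(2, 10), 1:10, rep(1, 10))$c, 0.5)
  # random censored instances match O(n^2) enumeration exactly
  set.seed(7)
  for (rep_i in 1:10) {
    n <- sample(20:120, 1)
    times <- round(rexp(n, 0.2), 2)
    events <- rbinom(n, 1, 0.7)
    scores <- round(rnorm(n), 1) # coarse scores force ties
    if (sum(events) == 0) events[1] <- 1
    got <- harrell_c(scores, times, events)
    expect_equal(got$c, brute_harrell_c(scores, times, events))
    expect_equal(
      got$concordant + got$discordant + got$tied,
      got$comparable_pairs
    )
  }
  # agreement with the survival package on an untied instance
  set.seed(8)
  n <- 150
  times <- rexp(n)
  events <- rbinom(n, 1, 0.6)
  events[1] <- 1
  scores <- rnorm(n)
  cf <- survival::concordance(survival::Surv(times, events) ~ scores)
  expect_equal(harrell_c(scores, times, events)$c, unname(cf$concordance))
})

test_that("Somers'-D comparison is calibrated at its boundaries and has power", {
  set.seed(5)
  n <- 400
  co <- fx_ph_cohort()[seq_len(n), ]
  times <- co$followup_years
  events <- co$death
  strong <- rank(times) + rnorm(n, sd = 5) # strongly informative
  noise <- rnorm(n)
  same <- compare_c(strong, strong, times, events)
  expect_equal(same$p_value, 1)
  expect_equal(same$difference, 0)
  cmp <- compare_c(strong, noise, times, events)
  expect_gte(cmp$se, 0)
  expect_lt(cmp$p_value, 0.05)
})

test_that("AUROC matches hand enumeration and pROC", {
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  set.seed(11)
  for (rep_i in 1:10) {
    n <- sample(30:150, 1)
    scores <- round(rnorm(n), 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    got <- auroc(scores, labels)
    expect_equal(got$auc, brute_auroc(scores, labels))
    ref <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
    expect_equal(got$auc, as.numeric(pROC::auc(ref)))
    expect_equal(got$variance, as.numeric(pROC::var(ref)), tolerance = 1e-9)
  }
  expect_error(auroc(1:4, c(1, 1, 1, 1)), class = "ihtsa_argument_error")
})

test_that("DeLong test agrees with pROC and is antisymmetric", {
  set.seed(13)
  n <- 300
  labels <- rbinom(n, 1, 0.3)
  labels[1:2] <- c(0, 1)
  s_good <- labels + rnorm(n)
  s_bad <- rnorm(n)
  ra <- auroc(s_good, labels)
  rb <- auroc(s_bad, labels)
  got <- delong_test(ra, rb)
  ref <- pROC::roc.test(
    pROC::roc(labels, s_good, quiet = TRUE, direction = "<"),
    pROC::roc(labels, s_bad, quiet = TRUE, direction = "<"),
    method = "delong"
  )
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
  # antisymmetry
  rev <- delong_test(rb, ra)
  expect_equal(rev$z, -got$z)
  expect_equal(rev$p_value, got$p_value)
  # identical scorers -> p = 1
  expect_equal(delong_test(ra, ra)$p_value, 1)
})

test_that("Hosmer-Lemeshow rejects miscalibration and respects preconditions", {
  set.seed(17)
  n <- 2000
  pred <- runif(n, 0.05, 0.6)
  # perfectly calibrated draw: large p-value most of the time
  hl_ok <- hosmer_lemeshow(pred, rbinom(n, 1, pred))
  expect_equal(hl_ok$dof, 8)
  expect_true(hl_ok$p_value > 0.001)
  # +0.2 uniform miscalibration: strong rejection
  shifted <- pmin(pred + 0.2, 1)
  hl_bad <- hosmer_lemeshow(shifted, rbinom(n, 1, pred))
  expect_lt(hl_bad$p_value, 0.05)
  expect_error(hosmer_lemeshow(pred, rbinom(n, 1, pred), g = 2),
    class = "ihtsa_argument_error"
  )
  expect_error(hosmer_lemeshow(c(-0.1, rep(0.5, 99)), rbinom(100, 1, 0.5)),
    class = "ihtsa_argument_error"
  )
})

test_that("logistic recalibration recovers identity and transformed slopes", {
  set.seed(19)
  n <- 10000
  pred <- plogis(rnorm(n, -1, 1))
  y <- rbinom(n, 1, pred)
  fit <- recalibrate_logistic(pred, y)
  expect_equal(fit$slope, 1, tolerance = 0.1)
  expect_equal(fit$intercept, 0, tolerance = 0.1)
  expect_false(fit$separation)
  # doubling the logit halves the recalibration slope
  pred2 <- plogis(2 * qlogis(pred))
  fit2 <- recalibrate_logistic(pred2, y)
  expect_equal(fit2$slope, 0.5, tolerance = 0.06)
  expect_error(recalibrate_logistic(rep(0.5, 100), rbinom(100, 1, 0.5)),
    class = "ihtsa_argument_error"
  )
})

test_that("Kaplan-Meier and log-rank match hand computations", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  # censoring at t=1: S(2) = 1/2, S(3) = 0
  km2 <- kaplan_meier(c(1, 2, 3), c(0, 1, 1))
  expect_equal(km2$survival[km2$time == 2], 0.5)
  expect_equal(km2$survival[km2$time == 3], 0)
  expect_true(all(km$failure == 1 - km$survival))
  # no events
  km3 <- kaplan_meier(c(1, 2), c(0, 0))
  expect_true(all(km3$survival == 1))
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), class = "ihtsa_argument_error")

  lr_same <- log_rank(c(1, 2, 3), c(1, 1, 0), c(1, 2, 3), c(1, 1, 0))
  expect_equal(lr_same$chi2, 0, tolerance = 1e-10)
  expect_equal(lr_same$p_value, 1, tolerance = 1e-6)
  set.seed(23)
  ta <- rexp(300, 0.1)
  tb <- rexp(300, 0.2)
  lr <- log_rank(ta, rep(1, 300), tb, rep(1, 300))
  swap <- log_rank(tb, rep(1, 300), ta, rep(1, 300))
  expect_equal(lr$chi2, swap$chi2)
  expect_lt(lr$p_value, 0.001)
  expect_error(log_rank(1:3, rep(0, 3), 4:6, rep(0, 3)),
    class = "ihtsa_argument_error"
  )
})

test_that("one-year labels exclude early censoring and count exclusions", {
  times <- c(0.5, 0.5, 1.5, 2.0, 1.0)
  events <- c(1, 0, 0, 1, 0)
  lab <- one_year_labels(times, events)
  expect_equal(lab$n_excluded, 1) # censored alive at 0.5
  expect_equal(lab$labels, c(1, 0, 0, 0))
})

test_that("C-index coincides with AUROC on all-event distinct-time data", {
  set.seed(29)
  n <- 80
  times <- sample(seq(0.1, 50, by = 0.1), n)
  events <- rep(1, n)
  scores <- rnorm(n)
  # label = death in the lower half of observed times; score threshold-free
  med <- median(times)
  labels <- as.numeric(times <= med)
  c_idx <- harrell_c(times, times, events)$c # perfect score
  expect_equal(c_idx, 1)
  # rank agreement between pair definitions on fully observed data
  c_sc <- harrell_c(scores, times, events)$c
  auc <- auroc(-scores, labels)$auc
  # both measure the same ordering; with a dichotomized label the AUROC is a
  # coarsening, so require qualitative agreement around 0.5
  expect_equal(c_sc > 0.5, auc > 0.5)
})
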