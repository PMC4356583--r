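# Discrete-time model: grid construction, likelihood expansion targets,
# network training against the life-table oracle, ensemble aggregation,
# survival-curve arithmetic and serialization.

test_that("time grid boundaries sit at equal-probability quantiles", {
  g <- build_time_grid(1:100, K = 4)
  expect_equal(g$boundaries, c(0, 25.75, 50.5, 75.25, 100))
  g1 <- build_time_grid(c(2, 9, 4), K = 1)
  expect_equal(g1$boundaries, c(0, 9))
  expect_warning(build_time_grid(rep(3, 50), K = 4), "merged")
  expect_error(build_time_grid(1:10, K = 0), class = "ihtsa_argument_error")
})

test_that("targets follow the discrete-time death/censoring conventions", {
  grid <- build_time_grid(seq(0.5, 5, by = 0.5), K = 5)
  grid$boundaries <- 0:5
  grid$K <- 5
  co <- tibble::tibble(
    followup_years = c(2.5, 2.5, 0.5, 5.0, 3.0),
    death = c(1, 0, 1, 0, 0)
  )
  tg <- make_targets(co, grid)
  # death inside interval 3: at risk 1..3, event in 3
  expect_equal(tg$at_risk[1, ], c(1, 1, 1, 0, 0))
  expect_equal(tg$event[1, ], c(0, 0, 1, 0, 0))
  # censored inside interval 3: at risk 1..2 only, no event
  expect_equal(tg$at_risk[2, ], c(1, 1, 0, 0, 0))
  expect_equal(sum(tg$event[2, ]), 0)
  # death inside interval 1
  expect_equal(tg$at_risk[3, ], c(1, 0, 0, 0, 0))
  expect_equal(tg$event[3, ], c(1, 0, 0, 0, 0))
  # censored exactly at the horizon: all K intervals fully survived
  expect_equal(tg$at_risk[4, ], rep(1, 5))
  expect_equal(sum(tg$event[4, ]), 0)
  # censored exactly on an interior boundary: intervals up to it survived
  expect_equal(tg$at_risk[5, ], c(1, 1, 1, 0, 0))
})

test_that("fitted hazards match the life-table estimator per group", {
  set.seed(42)
  n <- 3000
  x <- rbinom(n, 1, 0.5)
  h_true <- ifelse(x == 1, 0.2, 0.1)
  t <- numeric(n)
  d <- numeric(n)
  for (i in seq_len(n)) {
    ti <- 5
    for (k in 1:5) {
      if (runif(1) < h_true[i]) {
        ti <- k - 0.5
        d[i] <- 1
        break
      }
    }
    t[i] <- ti
  }
  co <- tibble::tibble(followup_years = t, death = d)
  grid <- structure(list(boundaries = 0:5, K = 5), class = "ihtsa_time_grid")
  tg <- make_targets(co, grid)
  xm <- scale(matrix(x, ncol = 1))
  net <- train_network(xm, tg,
    hidden = 3, decay = 1e-5,
    control = rprop_control(epochs = 300), seed = 2
  )
  h <- predict_hazard(net, xm)
  for (grp in 0:1) {
    life_table <- colSums(tg$event[x == grp, ]) /
      pmax(colSums(tg$at_risk[x == grp, ]), 1)
    expect_equal(unname(colMeans(h[x == grp, ])), life_table, tolerance = 0.02)
  }
  # same seed and data reproduce identical weights
  net2 <- train_network(xm, tg,
    hidden = 3, decay = 1e-5,
    control = rprop_control(epochs = 300), seed = 2
  )
  expect_identical(net$W1, net2$W1)
  expect_identical(net$W2, net2$W2)
  # accepted-loss sequence is nonincreasing
  expect_true(all(diff(net$accepted_loss) <= 0))
  # heavy decay shrinks hazards toward the covariate-free pooled hazard
  net_reg <- train_network(xm, tg,
    hidden = 3, decay = 1e5,
    control = rprop_control(epochs = 300), seed = 2
  )
  h_reg <- predict_hazard(net_reg, xm)
  pooled <- colSums(tg$event) / colSums(tg$at_risk)
  spread_reg <- max(abs(colMeans(h_reg[x == 1, ]) - colMeans(h_reg[x == 0, ])))
  spread_fit <- max(abs(colMeans(h[x == 1, ]) - colMeans(h[x == 0, ])))
  expect_lt(spread_reg, spread_fit / 4)
  expect_equal(unname(colMeans(h_reg)), pooled, tolerance = 0.05)
})

test_that("cross-validation selects by C-index with the documented tie rule", {
  co <- fx_ph_cohort()[1:1200, ]
  cv <- cross_validate(co,
    variables = c("vad", "icu"), K = 4,
    hidden_grid = 2, decay_grid = 1e-4, folds = 3,
    control = rprop_control(epochs = 120), seed = 3
  )
  expect_equal(cv$best_hidden, 2)
  expect_equal(nrow(cv$metrics), 1)
  expect_s3_class(cv$model, "ihtsa_ensemble")
  # pure-noise covariates give chance-level CV C-index
  cfg <- generator_config(
    n = 2000, true_log_hr = list(),
    time_varying = list(), seed = 19
  )
  noise <- generate_cohort(cfg)$cohort
  cvn <- cross_validate(noise,
    variables = c("icu", "diabetes", "pra_gt10"), K = 4,
    hidden_grid = 2, decay_grid = 1e-4, folds = 5,
    control = rprop_control(epochs = 120), seed = 5
  )
  expect_gt(cvn$metrics$value, 0.45)
  expect_lt(cvn$metrics$value, 0.55)
})

test_that("ensembles average member hazards and ignore member order", {
  model <- fx_small_model()
  co <- fx_ph_cohort()[1:50, ]
  cur <- predict_curve(model, co)
  h1 <- predict_hazard(
    model$members[[1]],
    design_transform(model$designs[[1]], co)
  )
  h2 <- predict_hazard(
    model$members[[2]],
    design_transform(model$designs[[2]], co)
  )
  expect_equal(cur$hazard, (h1 + h2) / 2)
  swapped <- model
  swapped$members <- rev(model$members)
  swapped$designs <- rev(model$designs)
  expect_equal(predict_curve(swapped, co)$hazard, cur$hazard)
  # single-member ensemble predicts exactly the member's hazards
  single <- model
  single$members <- model$members[1]
  single$designs <- model$designs[1]
  expect_equal(predict_curve(single, co)$hazard, h1)
  # hazards in (0,1), survival monotone from 1
  expect_true(all(cur$hazard > 0 & cur$hazard < 1))
  expect_true(all(cur$survival > 0 & cur$survival <= 1))
  expect_true(all(apply(cur$survival, 1, function(s) all(diff(s) <= 0))))
})

test_that("survival-curve arithmetic matches closed forms", {
  mk_curves <- function(h, boundaries) {
    hm <- matrix(h, nrow = 1)
    structure(
      list(
        boundaries = boundaries, hazard = hm,
        survival = t(apply(1 - hm, 1, cumprod))
      ),
      class = "ihtsa_curves"
    )
  }
  # two constant member hazards 0.1 and 0.3 average to 0.2: S_2 = 0.64
  cur <- mk_curves(rep(0.2, 3), 0:3)
  expect_equal(cur$survival[1, 2], 0.64)
  # constant hazard 0.1 over 25 intervals
  cur25 <- mk_curves(rep(0.1, 25), 0:25)
  expect_equal(cur25$survival[1, 25], 0.9^25)
  expect_equal(cur25$survival[1, 25], 0.0718, tolerance = 1e-3)
  # median interpolation: single interval [0,10] with S_1 = 0.25
  cur1 <- mk_curves(0.75, c(0, 10))
  med <- median_survival(cur1)
  expect_equal(med$median_years, 10 * (1 - 0.5) / (1 - 0.25), tolerance = 1e-12)
  expect_false(med$extrapolated)
  # S hitting exactly 0.5 at a boundary returns the boundary
  cur_exact <- mk_curves(c(0.5, 0.1), 0:2)
  expect_equal(median_survival(cur_exact)$median_years, 1)
  # S above 0.5 at the end: constant-rate extrapolation, flagged
  cur_hi <- mk_curves(c(0.1, 0.1), 0:2)
  med_hi <- median_survival(cur_hi)
  expect_true(med_hi$extrapolated)
  rate <- -log(0.9)
  expect_equal(
    med_hi$median_years,
    2 + log(0.81 / 0.5) / rate
  )
  # zero hazards: capped at the grid horizon with flag
  cur0 <- mk_curves(c(0, 0), 0:2)
  med0 <- median_survival(cur0)
  expect_true(med0$extrapolated)
  expect_equal(med0$median_years, 2, tolerance = 1e-6)
  # survival_at: exact at 0 and boundaries, linear at midpoints
  s <- survival_at(cur, c(0, 1, 1.5, 2))
  expect_equal(s$survival[1], 1)
  expect_equal(s$survival[2], 0.8)
  expect_equal(s$survival[3], mean(c(0.8, 0.64)))
  expect_equal(s$survival[4], 0.64)
  expect_error(survival_at(cur, -1), class = "ihtsa_argument_error")
  s_beyond <- survival_at(cur, 5)
  expect_true(s_beyond$extrapolated)
})

test_that("models serialize to JSON and reload bit-faithfully", {
  model <- fx_small_model()
  co <- fx_ph_cohort()[1:20, ]
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$grid$boundaries, model$grid$boundaries, tolerance = 1e-10)
  cur1 <- predict_curve(model, co)
  cur2 <- predict_curve(back, co)
  expect_equal(cur2$hazard, cur1$hazard, tolerance = 1e-10)
  expect_equal(cur2$survival, cur1$survival, tolerance = 1e-10)
})

test_that("tidiers expose curves, ensembles and concordance as tibbles", {
  model <- fx_small_model()
  co <- fx_ph_cohort()[1:10, ]
  cur <- predict_curve(model, co)
  td <- tidy(cur)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 10 * model$grid$K)
  gl <- glance(model)
  expect_equal(gl$members, 2)
  expect_equal(gl$intervals, 5)
  p <- autoplot(cur)
  expect_s3_class(p, "ggplot")
})
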