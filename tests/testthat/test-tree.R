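# CART on predicted median survival: planted-split recovery, pruning,
# importance accounting, routing and leaf validation.

fx_tree_data <- function(n = 2000, seed = 3, noise_sd = 0.3) {
  withr::with_seed(seed, {
    donor_age <- runif(n, 15, 65)
    icu <- rbinom(n, 1, 0.4)
    target <- ifelse(donor_age < 38, 14, 10) + rnorm(n, sd = noise_sd)
    list(
      features = tibble::tibble(
        donor_age = donor_age, icu = icu,
        diagnosis = sample(c("ischemic_cm", "non_ischemic_cm", "other"),
          n,
          replace = TRUE
        )
      ),
      target = target
    )
  })
}

test_that("a planted threshold split is recovered with dominant importance", {
  d <- fx_tree_data()
  tree <- fit_tree(d$features, d$target, min_leaf = 50)
  tree <- prune_tree(tree, 0.0035)
  splits <- ihtsa:::tree_split_table(tree)
  root <- splits[splits$node == 1, ]
  expect_equal(root$variable, "donor_age")
  # threshold within the grid resolution of the planted cutpoint
  root_split <- tree$rpart$splits[1, "index"]
  expect_lt(abs(root_split - 38), 1.5)
  imp <- tree_importance(tree)
  expect_equal(imp$variable[1], "donor_age")
  expect_gt(imp$importance[1], 0.95)
})

test_that("constant targets give a single leaf; huge cc_alpha collapses to root", {
  d <- fx_tree_data()
  tree_const <- fit_tree(d$features, rep(5, nrow(d$features)), min_leaf = 50)
  lv <- tree_leaves(tree_const)
  expect_equal(nrow(lv), 1)
  expect_equal(lv$predicted_median, 5)
  tree <- fit_tree(d$features, d$target, min_leaf = 50)
  expect_identical(prune_tree(tree, 0), tree)
  rooted <- prune_tree(tree, 1e6)
  expect_equal(nrow(tree_leaves(rooted)), 1)
  expect_equal(nrow(tree_importance(rooted)), 0)
  # min_leaf >= n: single leaf, not an error
  tree_big <- fit_tree(d$features, d$target, min_leaf = nrow(d$features))
  expect_equal(nrow(tree_leaves(tree_big)), 1)
  expect_error(fit_tree(d$features, c(NA, d$target[-1])),
    class = "ihtsa_argument_error"
  )
})

test_that("importance sums to the explained-variance fraction (<= 1)", {
  withr::with_seed(11, {
    n <- 1500
    a <- runif(n)
    b <- runif(n)
    target <- 3 * (a > 0.5) + 1 * (b > 0.5) + rnorm(n, sd = 0.2)
  })
  feats <- tibble::tibble(a = a, b = b)
  tree <- prune_tree(fit_tree(feats, target, min_leaf = 40), 0.0035)
  imp <- tree_importance(tree)
  expect_true(all(c("a", "b") %in% imp$variable))
  expect_equal(imp$variable[1], "a") # larger planted effect ranks first
  total <- sum(imp$importance)
  expect_lte(total, 1)
  # total importance equals 1 - SSE(leaves)/SSE(root)
  lv_idx <- tree$rpart$frame$var == "<leaf>"
  sse_leaves <- sum(tree$rpart$frame$dev[lv_idx])
  expect_equal(total, 1 - sse_leaves / tree$root_sse, tolerance = 1e-10)
})

test_that("pruned leaves are a coarsening and predictions equal leaf means", {
  d <- fx_tree_data(noise_sd = 1.5)
  tree <- fit_tree(d$features, d$target, min_leaf = 30)
  pruned <- prune_tree(tree, 0.01)
  leaves_full <- ihtsa:::route_to_leaves(tree, d$features)
  leaves_pruned <- ihtsa:::route_to_leaves(pruned, d$features)
  # records sharing a full-tree leaf stay together after pruning
  tab <- table(leaves_full, leaves_pruned)
  expect_true(all(rowSums(tab > 0) == 1))
  # per-record prediction = training-target mean of its leaf
  pred <- predict(tree$rpart, cbind(d$features))
  agg <- tapply(d$target, leaves_full, mean)
  expect_equal(unname(pred), as.numeric(agg[as.character(leaves_full)]),
    tolerance = 1e-10
  )
  # routing agrees with rpart's own training assignment
  own <- as.integer(rownames(tree$rpart$frame))[tree$rpart$where]
  expect_equal(leaves_full, own)
})

test_that("leaf validation runs KM and log-rank per leaf across cohorts", {
  co <- fx_ph_cohort()
  model <- fx_small_model()
  med <- predicted_median_survival(model, co)$median_years
  feats <- co[, c("vad", "recipient_age", "creatinine")]
  tree <- prune_tree(fit_tree(feats, med, min_leaf = 100), 0.0035)
  sp <- split_cohort(co, c(0.6, 0.4), seed = 3)
  res <- validate_leaves(tree, sp$dc, sp$ivc)
  expect_true(nrow(res$log_rank) >= 1)
  expect_true(all(res$log_rank$p_value >= 0 & res$log_rank$p_value <= 1,
    na.rm = TRUE
  ))
  # same-cohort comparison: survival curves coincide per leaf
  res_same <- validate_leaves(tree, co, co)
  expect_true(all(res_same$log_rank$chi2 < 1e-10))
  expect_true(all(res_same$log_rank$p_value > 0.999))
})
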