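# Allocation simulator: ABO rules, clinical tiers, policy argmax behaviour,
# conservation invariants and determinism.

test_that("ABO compatibility follows the standard donor-recipient table", {
  # identity: every group can donate to itself
  for (g in c("A", "AB", "B", "O")) expect_true(abo_compatible(g, g))
  expect_true(abo_compatible("O", "A"))
  expect_true(abo_compatible("O", "AB"))
  expect_false(abo_compatible("AB", "O"))
  expect_false(abo_compatible("A", "B"))
  expect_true(abo_compatible("B", "AB"))
  expect_false(abo_compatible("B", "A"))
  expect_error(abo_compatible("X", "A"), class = "ihtsa_argument_error")
})

test_that("clinical tiers reproduce the criterion walk-throughs", {
  donor <- list(
    donor_bg = "A", donor_age = 30, donor_weight = 75,
    donor_sex = "male"
  )
  rec1 <- list(
    recipient_bg = "A", recipient_age = 34, recipient_weight = 70,
    recipient_sex = "male", pvr = 2.0
  )
  expect_equal(clinical_priority(donor, rec1), 1L)
  # PVR 3.5: donor 7.1% heavier is inside the 0-15% window, ages -> tier 2
  rec2 <- list(
    recipient_bg = "A", recipient_age = 50, recipient_weight = 70,
    recipient_sex = "male", pvr = 3.5
  )
  expect_equal(clinical_priority(donor, rec2), 2L)
  # female donor to male recipient is excluded under PVR > 3
  donor_f <- donor
  donor_f$donor_sex <- "female"
  out <- clinical_priority(donor_f, rec2)
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "female-to-male")
  # weight outside +/-20%
  rec3 <- rec1
  rec3$recipient_weight <- 50
  expect_true(is.na(clinical_priority(donor, rec3)))
  # compatible but non-identical group falls to tier 3
  donor_o <- donor
  donor_o$donor_bg <- "O"
  expect_equal(clinical_priority(donor_o, rec1), 3L)
  # missing fields are ineligible with a recorded reason
  rec4 <- rec1
  rec4$pvr <- NA
  expect_true(is.na(clinical_priority(donor, rec4)))
})

test_that("allocation picks the argmax predicted median for the model policy", {
  model <- fx_small_model()
  pool <- fx_ph_cohort()
  waitlist <- pool[1:30, ]
  donor <- pool[101, ]
  res <- allocate_donor(donor, waitlist, "ihtsa", model = model, tie_u = 0.2)
  # brute-force: score every compatible candidate as a hypothetical pair
  comp <- which(abo_compatible(
    rep(donor$donor_bg, 30),
    waitlist$recipient_bg
  ))
  pairs <- waitlist[comp, ]
  pairs$donor_age <- donor$donor_age
  pairs$donor_sex <- donor$donor_sex
  pairs$donor_weight <- donor$donor_weight
  pairs$donor_bg <- donor$donor_bg
  pairs$codd_head_trauma <- donor$codd_head_trauma
  pairs$codd_cva <- donor$codd_cva
  pairs$ischemia_min <- median(pool$ischemia_min)
  med <- predicted_median_survival(model, pairs)$median_years
  expect_equal(res$index, comp[which.max(med)])
  expect_equal(res$predicted_median, max(med), tolerance = 1e-4)
  # single eligible candidate is chosen by every policy
  one <- waitlist[comp[1], ]
  one$recipient_bg <- donor$donor_bg
  one$recipient_weight <- donor$donor_weight
  one$pvr <- 2.0
  for (p in c("ihtsa", "clinical", "random")) {
    r1 <- allocate_donor(donor, one, p,
      model = if (p == "ihtsa") model else NULL, tie_u = 0.9
    )
    expect_equal(r1$index, 1L)
  }
})

test_that("simulation runs are conservative, seeded and policy-ordered", {
  model <- fx_small_model()
  pool <- fx_ph_cohort()
  run <- run_simulation(pool,
    nw = 15, n_donor_draws = 60,
    policies = c("ihtsa", "clinical", "random"),
    model = model, seed = 31
  )
  expect_true(all(run$summary$transplants <= run$n_donor_draws))
  # each policy's matched recipients are distinct pool rows
  for (p in run$policies) {
    m <- run$matches[run$matches$policy == p, ]
    expect_equal(anyDuplicated(m$recipient_row), 0)
  }
  # byte-identical reproduction under the same seed
  run2 <- run_simulation(pool,
    nw = 15, n_donor_draws = 60,
    policies = c("ihtsa", "clinical", "random"),
    model = model, seed = 31
  )
  expect_identical(run$matches, run2$matches)
  expect_identical(run$summary, run2$summary)
  # the model policy cannot transplant fewer organs than the clinical one
  # (it refuses no eligible ABO-compatible donor)
  s <- run$summary
  expect_gte(
    s$transplants[s$policy == "ihtsa"],
    s$transplants[s$policy == "clinical"]
  )
})

test_that("a sole incompatible recipient yields zero transplants", {
  model <- fx_small_model()
  pool <- fx_ph_cohort()
  # waiting list of 1 with recipient O; force every donor AB (incompatible)
  pool_ab <- pool
  pool_ab$donor_bg <- "AB"
  pool_ab$recipient_bg <- "O"
  run <- run_simulation(pool_ab,
    nw = 1, n_donor_draws = 10,
    policies = c("random"), model = NULL, seed = 1
  )
  expect_equal(run$summary$transplants, 0)
})

test_that("sensitivity filter drops the configured high-risk fraction", {
  pool <- fx_ph_cohort()
  filtered <- sensitivity_filter(pool)
  expect_true(all(filtered$icu == 0 & filtered$ventilator == 0 &
    filtered$ecmo == 0 & filtered$vad == 0))
  hi_risk <- mean(pool$icu == 1 | pool$ventilator == 1 |
    pool$ecmo == 1 | pool$vad == 1)
  expect_equal(1 - nrow(filtered) / nrow(pool), hi_risk)
  # identity predicate
  expect_identical(sensitivity_filter(pool, function(p) rep(FALSE, nrow(p))), pool)
  expect_error(sensitivity_filter(pool, function(p) rep(TRUE, nrow(p))),
    class = "ihtsa_argument_error"
  )
})
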