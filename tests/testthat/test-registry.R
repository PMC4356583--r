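# Cohort data model: CSV round-trips, the derivation/validation split,
# half-IQR increments and design-matrix construction.

test_that("cohort CSV round-trips cell-for-cell, missing cells included", {
  cfg <- generator_config(
    n = 20,
    missing_rates = c(creatinine = 0.4, pvr = 0.3), seed = 3
  )
  co <- inject_missingness(generate_cohort(cfg)$cohort, cfg)
  expect_true(anyNA(co$creatinine))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(co),
    tolerance = 1e-12, ignore_attr = TRUE
  )
  # empty cell convention: NA cells round-trip as missing flags
  expect_identical(is.na(back$creatinine), is.na(co$creatinine))
})

test_that("schema violations are rejected with informative errors", {
  co <- fx_tiny_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co[, setdiff(names(co), "death")], path)
  expect_error(read_cohort(path), class = "ihtsa_schema_error")

  co2 <- co
  co2$bogus <- 1
  expect_error(validate_cohort(co2), class = "ihtsa_schema_error")
  expect_silent(validate_cohort(co2, allow_extra = TRUE))

  co3 <- co
  co3$recipient_bg[1] <- "Z"
  expect_error(validate_cohort(co3), class = "ihtsa_parse_error")

  co4 <- co
  co4$era[2] <- NA
  expect_error(validate_cohort(co4), class = "ihtsa_schema_error")
})

test_that("split_cohort partitions exhaustively with the rounding contract", {
  co <- fx_tiny_cohort(n = 100, seed = 9)
  sp <- split_cohort(co, c(0.83, 0.17), seed = 7)
  expect_equal(nrow(sp$dc), 83)
  expect_equal(nrow(sp$ivc), 17)
  # disjoint and exhaustive: cell-level reassembly matches the input
  all_rows <- dplyr::bind_rows(sp$dc, sp$ivc)
  expect_equal(nrow(all_rows), nrow(co))
  expect_equal(
    dplyr::arrange(all_rows, .data$followup_years, .data$recipient_age, .data$creatinine),
    dplyr::arrange(co, .data$followup_years, .data$recipient_age, .data$creatinine),
    ignore_attr = TRUE
  )
  # determinism
  sp2 <- split_cohort(co, c(0.83, 0.17), seed = 7)
  expect_identical(sp$dc$followup_years, sp2$dc$followup_years)
  # a different seed gives a different partition
  sp3 <- split_cohort(co, c(0.83, 0.17), seed = 8)
  expect_false(identical(sp$dc$followup_years, sp3$dc$followup_years))
  expect_error(split_cohort(co, c(1.2, -0.2)), class = "ihtsa_argument_error")
  # the registry's published derivation fraction is reproduced by rounding
  expect_equal(round(41780 / (41780 + 8569), 2), 0.83)
})

test_that("half-IQR increments reproduce the published steps", {
  # quartiles exactly 88 / 132 (creatinine, umol/l) -> step 22
  creat <- c(44, 88, 106, 132, 176)
  expect_equal(half_iqr_increment(creat), 22)
  # quartiles exactly 22 / 44 (donor age, years) -> step 11
  dage <- c(10, 22, 34, 44, 60)
  expect_equal(half_iqr_increment(dage), 11)
  # half-up rounding at .5 (banker's rounding would give 2 here)
  expect_equal(half_iqr_increment(c(0, 0, 5, 5)), 3)
  vals <- c(1, 2, 3, 4) # IQR = 1.5 -> 0.75 -> rounds to 1
  expect_equal(half_iqr_increment(vals), 1)
  expect_equal(half_iqr_increment(vals, round_to_integer = FALSE), 0.75)
  # degenerate constant sample
  inc <- half_iqr_increment(rep(7, 10))
  expect_equal(as.numeric(inc), 0)
  expect_true(attr(inc, "degenerate"))
  expect_error(half_iqr_increment(c(NA, NA, NA, NA)), class = "ihtsa_argument_error")
})

test_that("design matrix uses reference coding, standardization and ratios", {
  co <- fx_tiny_cohort(n = 200, seed = 13)
  d <- build_design(co)
  # recipient blood group vs reference AB -> indicator columns A, B, O
  expect_true(all(c("recipient_bg_A", "recipient_bg_B", "recipient_bg_O")
  %in% d$column_names))
  expect_false("recipient_bg_AB" %in% d$column_names)
  # donor blood group vs reference A -> B, AB, O
  expect_true(all(c("donor_bg_B", "donor_bg_AB", "donor_bg_O")
  %in% d$column_names))
  expect_false("donor_bg_A" %in% d$column_names)
  # era dichotomized to 3 indicators vs the earliest era
  expect_equal(sum(startsWith(d$column_names, "era_")), 3)
  # indicator block sums: one-hot or all-zero (reference) per record
  bg_cols <- d$x[, startsWith(d$column_names, "recipient_bg_")] *
    d$scales[startsWith(d$column_names, "recipient_bg_")] # undo scaling (none)
  expect_true(all(rowSums(bg_cols) <= 1))
  # all-reference record encodes to zero indicators
  ref_row <- co[1, ]
  ref_row$recipient_bg <- "AB"
  ref_row$donor_bg <- "A"
  ref_row$era <- "1991-1995"
  ref_row$diagnosis <- "non_ischemic_cm"
  ref_row$hladr_mismatch <- "0"
  ref_row$recipient_sex <- "male"
  ref_row$donor_sex <- "male"
  xr <- design_transform(d, ref_row)
  ind <- grepl("_(A|AB|B|O|0|1|2|1996_2000|2001_2005|2006_2010|female)$", d$column_names) |
    startsWith(d$column_names, "diagnosis_")
  expect_true(all(xr[, ind] == 0))
  # continuous columns standardized at fit time
  cont <- d$column_kinds == "continuous"
  expect_true(all(abs(colMeans(d$x[, cont])) < 1e-10))
  expect_true(all(abs(apply(d$x[, cont], 2, sd) - 1) < 1e-10))
  # derived ratio present and correct on the raw scale
  j <- match("weight_ratio", d$column_names)
  raw <- d$x[, j] * d$scales[j] + d$centers[j]
  expect_equal(raw, co$recipient_weight / co$donor_weight)
})

test_that("design transform reproduces the fit-time matrix exactly", {
  co <- fx_tiny_cohort(n = 60, seed = 17)
  d <- build_design(co)
  expect_identical(design_transform(d, co), d$x)
  # missing model variable at transform time is a prediction error
  co_na <- co
  co_na$creatinine[3] <- NA
  expect_error(design_transform(d, co_na), class = "ihtsa_prediction_error")
})
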