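# Scenario loading, validation and the bundled country fixtures.

test_that("bundled fixtures validate with zero violations", {
  for (cty in c("china", "us")) {
    s <- bundled_scenario(cty)
    expect_s3_class(s, "cea_scenario")
    expect_identical(validate_scenario(s), character(0))
  }
})

test_that("the China fixture transcribes the printed parameter tables", {
  s <- bundled_scenario("china")
  expect_equal(s$settings$cycle_days, 21)
  expect_equal(s$settings$horizon_years, 5)
  expect_equal(s$settings$annual_discount_rate, 0.03)
  expect_equal(s$settings$wtp_per_qaly, 3 * 12741)
  expect_equal(s$settings$gdp_per_capita, 12741)

  expect_equal(s$utilities$stable$base, 0.74)
  expect_equal(s$utilities$remission$base, 0.85)
  expect_equal(s$utilities$relapse$base, 0.50)
  expect_equal(s$utilities$death$base, 0)

  tala <- s$arms$intervention
  expect_equal(unlist(tala$survival[c("rr", "os_months", "pfs_months", "dor_months")]),
               c(rr = 0.646, os_months = 24.3, pfs_months = 8.6, dor_months = 5.4))
  expect_equal(tala$drug_cost$talazoparib$base, 3440.97)
  expect_equal(tala$drug_cost$talazoparib$low, 2752.78)
  expect_equal(tala$drug_cost$talazoparib$high, 4129.16)
  expect_equal(vapply(tala$ae_profile, `[[`, 0, "incidence"),
               c(anaemia = 0.66, neutropenia = 0.36, fatigue = 0.34,
                 back_pain = 0.22, nausea = 0.21))
  expect_equal(vapply(tala$ae_profile, function(e) e$cost$base, 0),
               c(anaemia = 532.96, neutropenia = 412, fatigue = 81.57,
                 back_pain = 11.11, nausea = 64))

  st <- s$arms$comparator
  expect_equal(unlist(st$survival[c("rr", "os_months", "pfs_months", "dor_months")]),
               c(rr = 0.111, os_months = 6.3, pfs_months = 5.6, dor_months = 3.1))
  expect_equal(vapply(st$drug_cost, `[[`, 0, "weight"),
               c(capecitabine = 0.44, eribulin = 0.40, gemcitabine = 0.10,
                 vinorelbine = 0.07))
  expect_equal(vapply(st$drug_cost, `[[`, 0, "base"),
               c(capecitabine = 9.31, eribulin = 2481.76, gemcitabine = 153.15,
                 vinorelbine = 170.03))
  expect_equal(vapply(st$ae_profile, `[[`, 0, "incidence"),
               c(anaemia = 0.17, neutropenia = 0.07, fatigue = 0.29,
                 back_pain = 0.18, nausea = 0.12))

  expect_equal(vapply(s$cost_table, `[[`, 0, "base"),
               c(laboratory_testing = 75.47, ct_scan = 47.23,
                 nursing_fee = 184.82, routine_follow_up = 7.05,
                 docetaxel = 884.92, prednisone = 0.52,
                 brca_profiling = 1378.58))
  expect_equal(st$transition_sa$relapse_to_death,
               list(low = 0.4193, high = 0.6289))
  expect_equal(tala$transition_sa$remission_to_relapse,
               list(low = 0.0734, high = 0.1101))
})

test_that("the US fixture transcribes the printed parameter tables", {
  s <- bundled_scenario("us")
  expect_equal(s$settings$wtp_per_qaly, 3 * 76400)
  expect_equal(s$cost_table$brca_profiling$base, 1380.17)
  expect_equal(vapply(s$cost_table, `[[`, 0, "base"),
               c(laboratory_testing = 12.675, ct_scan = 828,
                 bone_imaging = 253.46, nursing_fee = 1617,
                 routine_follow_up = 422, docetaxel = 2228.95,
                 prednisone = 23.4, brca_profiling = 1380.17))
  # inconsistent printed lab-testing range is present but flagged fixed
  expect_equal(s$cost_table$laboratory_testing$family, "fixed")
  expect_equal(vapply(s$arms$comparator$drug_cost, `[[`, 0, "base"),
               c(capecitabine = 6.38, eribulin = 2481.76, gemcitabine = 1195.48,
                 vinorelbine = 103.82))
  expect_equal(vapply(s$arms$intervention$ae_profile, function(e) e$cost$base, 0),
               c(anaemia = 1134.10, neutropenia = 7818, fatigue = 9857.88,
                 back_pain = 12534.53, nausea = 719.54))
  # shares the talazoparib drug row with the China table, as printed
  expect_equal(s$arms$intervention$drug_cost$talazoparib$base, 3440.97)
})

test_that("YAML round trip is the identity", {
  for (cty in c("china", "us")) {
    s <- bundled_scenario(cty)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_scenario(s, path)
    expect_equal(read_scenario(path), s, tolerance = 1e-12)
  }
  # and for programmatically generated scenarios with perturbed costs
  set.seed(42)
  for (i in 1:5) {
    s <- make_test_scenario(drug_intervention = runif(1, 10, 5000),
                            discount = runif(1, 0, 0.1))
    s$cost_table <- perturb_cost_table(s$cost_table, 0.2)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_scenario(s, path)
    expect_equal(read_scenario(path), s, tolerance = 1e-9)
  }
})

test_that("a missing response rate is derived from OS and PFS on load", {
  s <- make_test_scenario()
  s$arms$comparator$survival$rr <- NULL
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(s, path)
  loaded <- read_scenario(path)
  expect_equal(loaded$arms$comparator$survival$rr, (6.3 - 5.6) / 6.3,
               tolerance = 1e-12)
})

test_that("validation reports violations without throwing", {
  s <- make_test_scenario()
  s$arms$comparator$survival$pfs_months <- s$arms$comparator$survival$os_months
  v <- validate_scenario(s)
  expect_length(v, 1)
  expect_match(v, "SurvivalSummary \\(comparator\\)")

  s2 <- make_test_scenario()
  s2$utilities$remission$base <- 1.2   # beta base outside its range
  expect_match(validate_scenario(s2), "outside", all = FALSE)

  s3 <- make_test_scenario()
  s3$cost_table <- NULL
  expect_match(validate_scenario(s3), "cost_table", all = FALSE)

  s4 <- make_test_scenario()
  s4$settings$wtp_per_qaly <- NULL
  expect_match(validate_scenario(s4), "wtp_per_qaly", all = FALSE)

  # renormalizable mixture weights are accepted as printed (sum 101%)
  expect_identical(validate_scenario(bundled_scenario("china")), character(0))
})

test_that("loading an invalid scenario names the violated field", {
  s <- make_test_scenario()
  s$utilities$relapse$base <- 1.2
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(s, path)
  expect_error(read_scenario(path), "UtilitySet \\(relapse\\)")
  expect_error(read_scenario(file.path(tempdir(), "does-not-exist.yaml")),
               "not found")
})
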