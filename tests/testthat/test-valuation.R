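# Valuation: discounting, per-state costing, arm totals.

test_that("discount factors follow the annual rate on the cycle grid", {
  expect_equal(discount_factor(0, 0.03, 21), 1)
  expect_equal(discount_factor(0, 0.8, 365), 1)
  expect_equal(discount_factor(1, 0.03, 365.25), 1 / 1.03, tolerance = 1e-12)
  d <- discount_factor(0:87, 0.03, 21)
  expect_true(all(diff(d) < 0))
  expect_equal(discount_factor(0:87, 0, 21), rep(1, 88))
})

test_that("expected adverse-event cost is the incidence-weighted sum", {
  profile <- bundled_scenario("china")$arms$intervention$ae_profile
  # independent arithmetic over the printed incidences and unit costs
  expect_equal(expected_ae_cost(profile),
               0.66 * 532.96 + 0.36 * 412 + 0.34 * 81.57 + 0.22 * 11.11 +
                 0.21 * 64.00,
               tolerance = 1e-12)
  zero <- lapply(profile, function(e) { e$incidence <- 0; e })
  expect_equal(expected_ae_cost(zero), 0)
  double <- lapply(profile, function(e) { e$incidence <- 2 * e$incidence; e })
  expect_equal(expected_ae_cost(double), 2 * expected_ae_cost(profile),
               tolerance = 1e-12)
  expect_equal(expected_ae_cost(list()), 0)
})

test_that("mixture drug cost renormalizes the printed shares", {
  w <- c(0.44, 0.40, 0.10, 0.07)
  costs <- c(9.31, 2481.76, 153.15, 170.03)
  # independent arithmetic: weights divided by their 1.01 total
  expect_equal(mix_cycle_cost(w, costs), sum(w / 1.01 * costs),
               tolerance = 1e-12)
  expect_equal(mix_cycle_cost(w, costs), 1013.878713, tolerance = 1e-6)
  expect_equal(mix_cycle_cost(1, 42.5), 42.5)
  perm <- sample(4)
  expect_equal(mix_cycle_cost(w[perm], costs[perm]), mix_cycle_cost(w, costs),
               tolerance = 1e-12)
  expect_error(mix_cycle_cost(numeric(0), numeric(0)), "non-empty")
  expect_error(mix_cycle_cost(c(0.5, -0.1), c(1, 2)), "positive")
})

test_that("state cycle costs follow the China cost table", {
  s <- bundled_scenario("china")
  np <- 75.47 + 47.23 + 184.82 + 7.05
  expect_equal(state_cycle_cost("STABLE", s$arms$intervention, s),
               3440.97 + np, tolerance = 1e-9)
  expect_equal(state_cycle_cost("REMISSION", s$arms$intervention, s),
               3440.97 + np, tolerance = 1e-9)
  expect_equal(state_cycle_cost("RELAPSE", s$arms$intervention, s),
               884.92 + 0.52 + np, tolerance = 1e-9)
  for (cty in c("china", "us")) {
    sc <- bundled_scenario(cty)
    expect_equal(state_cycle_cost("DEATH", sc$arms$intervention, sc), 0)
  }
  expect_error(state_cycle_cost("LIMBO", s$arms$intervention, s), "unknown state")
})

test_that("arm valuation equals the brute-force per-cycle oracle", {
  for (cty in c("china", "us")) {
    s <- bundled_scenario(cty)
    for (a in c("intervention", "comparator")) {
      fit <- arm_fit(s, a)
      oracle <- brute_force_arm_value(fit$trace, s$arms[[a]], s)
      expect_equal(fit$result$total_cost_usd, oracle$total_cost_usd,
                   tolerance = 1e-9)
      expect_equal(fit$result$total_qaly, oracle$total_qaly, tolerance = 1e-9)
      expect_equal(Reduce(`+`, fit$result$breakdown),
                   fit$result$total_cost_usd, tolerance = 0.01)
    }
  }
})

test_that("a deathless full-health undiscounted cohort accrues the horizon", {
  s <- make_test_scenario(discount = 0, utilities = c(stable = 1,
                                                      remission = 1,
                                                      relapse = 1),
                          drug_intervention = 0, drug_comparator = 0,
                          pd_cost = 0, np_cost = 0, oneoff_cost = 0,
                          ae_incidence = 0)
  n <- n_cycles(s$settings)
  stay <- structure(diag(4), dimnames = list(cea_states(), cea_states()))
  trace <- run_cohort(stay, n = n, cycle_days = s$settings$cycle_days,
                      half_cycle = TRUE)
  res <- evaluate_arm(trace, s$arms$intervention, s)
  expect_equal(res$total_qaly, n * 21 / 365.25, tolerance = 1e-12)
  expect_equal(res$total_cost_usd, 0)
})

test_that("QALYs are bounded by horizon times the maximum utility", {
  for (cty in c("china", "us")) {
    s <- bundled_scenario(cty)
    for (a in c("intervention", "comparator")) {
      res <- arm_fit(s, a)$result
      expect_lte(res$total_qaly, s$settings$horizon_years * 0.85)
      expect_gte(res$total_qaly, 0)
    }
  }
})

test_that("raising the discount rate lowers both totals", {
  base <- make_test_scenario(discount = 0.03)
  high <- make_test_scenario(discount = 0.08)
  for (a in c("intervention", "comparator")) {
    r0 <- arm_fit(base, a)$result
    r1 <- arm_fit(high, a)$result
    expect_lt(r1$total_cost_usd, r0$total_cost_usd)
    expect_lt(r1$total_qaly, r0$total_qaly)
  }
})

test_that("per-cycle costs scale linearly", {
  s1 <- make_test_scenario(drug_intervention = 100, pd_cost = 30, np_cost = 10,
                           oneoff_cost = 0, ae_incidence = 0)
  s2 <- make_test_scenario(drug_intervention = 300, pd_cost = 90, np_cost = 30,
                           oneoff_cost = 0, ae_incidence = 0)
  r1 <- arm_fit(s1)$result
  r2 <- arm_fit(s2)$result
  expect_equal(r2$total_cost_usd, 3 * r1$total_cost_usd, tolerance = 1e-9)
})

test_that("trace and scenario cycle lengths must agree", {
  s <- bundled_scenario("china")
  m <- build_matrix(s$arms$intervention$survival)
  tr <- run_cohort(m, n = 10, cycle_days = 30)
  expect_error(evaluate_arm(tr, s$arms$intervention, s), "cycle length")
})

test_that("the dose audit helper reconstructs printed-scale cycle costs", {
  # talazoparib 1 mg daily for a 21-day cycle at the printed unit price:
  # close to, but not exactly, the printed per-cycle value
  audit <- dose_based_cycle_cost(163.85, 1, 21)
  expect_equal(audit, 3440.85, tolerance = 1e-9)
  expect_equal(abs(audit - 3440.97) < 0.5, TRUE)
})
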