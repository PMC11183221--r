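# Programmatic fixtures: a fully controllable small scenario and an
# independent brute-force valuation oracle.

test_dist <- function(base, family = "gamma") {
  list(family = family, base = base, low = 0.9 * base, high = 1.1 * base)
}

# A complete, valid scenario built in code, with every economic lever
# exposed so tests can isolate one mechanism at a time.
make_test_scenario <- function(discount = 0.03,
                               utilities = c(stable = 0.74, remission = 0.85,
                                             relapse = 0.5),
                               drug_intervention = 100, drug_comparator = 50,
                               pd_cost = 30, np_cost = 10, oneoff_cost = 20,
                               ae_incidence = 0.5, ae_cost = 40,
                               wtp = 1000, half_cycle = TRUE,
                               horizon_years = 1, cycle_days = 21,
                               stable_to_death = 0) {
  mk_arm <- function(name, survival, drug) {
    list(name = name, survival = survival,
         drug_cost = stats::setNames(
           list(c(test_dist(drug, "triangular"), list(weight = 1))), name),
         ae_profile = list(
           event_a = list(incidence = ae_incidence, cost = test_dist(ae_cost))))
  }
  structure(list(
    country = "test",
    settings = list(cycle_days = cycle_days, horizon_years = horizon_years,
                    annual_discount_rate = discount,
                    half_cycle_correction = half_cycle,
                    stable_to_death = stable_to_death,
                    wtp_per_qaly = wtp, gdp_per_capita = wtp / 3),
    utilities = list(
      stable = test_dist(utilities[["stable"]], "beta"),
      remission = test_dist(utilities[["remission"]], "beta"),
      relapse = test_dist(utilities[["relapse"]], "beta"),
      death = list(family = "fixed", base = 0, low = 0, high = 0)),
    arms = list(
      intervention = mk_arm("drugA",
        list(rr = 0.646, os_months = 24.3, pfs_months = 8.6, dor_months = 5.4),
        drug_intervention),
      comparator = mk_arm("drugB",
        list(rr = 0.111, os_months = 6.3, pfs_months = 5.6, dor_months = 3.1),
        drug_comparator)),
    cost_table = list(
      nonpharma = c(list(applies_to = "all_alive"), test_dist(np_cost)),
      pd_therapy = c(list(applies_to = "progressed_state"), test_dist(pd_cost)),
      profiling = c(list(applies_to = "one_off"),
                    test_dist(oneoff_cost, "triangular")))),
    class = "cea_scenario")
}

# Brute-force valuation oracle: explicit double loop over cycles and
# states through the public per-state costing helpers; written as a
# second, independent route to the same totals.
brute_force_arm_value <- function(trace, arm, scenario) {
  set <- scenario$settings
  u <- c(scenario$utilities$stable$base, scenario$utilities$remission$base,
         scenario$utilities$relapse$base, scenario$utilities$death$base)
  occ <- trace$occupancy
  total_cost <- 0
  total_qaly <- 0
  for (k in 0:(nrow(occ) - 1)) {
    d <- (1 + set$annual_discount_rate)^(-(k * set$cycle_days / 365.25))
    w <- trace$weights[k + 1]
    for (s in seq_along(cea_states())) {
      c_s <- state_cycle_cost(cea_states()[s], arm, scenario)
      total_cost <- total_cost + w * d * occ[k + 1, s] * c_s
      total_qaly <- total_qaly + w * d * occ[k + 1, s] * u[s] *
        set$cycle_days / 365.25
    }
  }
  oneoff <- expected_ae_cost(arm$ae_profile) +
    sum(vapply(Filter(function(i) identical(i$applies_to, "one_off"),
                      scenario$cost_table), function(i) i$base, 0))
  list(total_cost_usd = total_cost + oneoff, total_qaly = total_qaly)
}

# Trace + valuation for one arm of a scenario, via the public API.
arm_fit <- function(scenario, which = "intervention") {
  set <- scenario$settings
  arm <- scenario$arms[[which]]
  m <- build_matrix(arm$survival, stable_to_death = set$stable_to_death)
  trace <- run_cohort(m, n = n_cycles(set), cycle_days = set$cycle_days,
                      half_cycle = isTRUE(set$half_cycle_correction))
  list(matrix = m, trace = trace, result = evaluate_arm(trace, arm, scenario))
}
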