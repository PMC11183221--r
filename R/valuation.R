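# Valuation: convert a cohort trace into total discounted cost (USD) and
# discounted QALYs for one arm under one country scenario.
#
# Accrual conventions: drug and non-pharmaceutical costs accrue per cycle
# while alive in the relevant states (progressed-state therapy replaces the
# arm drug after relapse); BRCA profiling and the expected adverse-event
# cost are charged once, undiscounted, at model entry.  No terminal-care
# cost is charged in the cycle of death.

#' Per-cycle discount factor
#'
#' `(1 + annual_rate)^(-cycle_index * cycle_days / 365.25)`.
#'
#' @param cycle_index Cycle number(s), 0-based (vectorized).
#' @param annual_rate Annual discount rate (default 0.03).
#' @param cycle_days Cycle length in days.
#' @return Discount factor(s) in `(0, 1]`.
#' @export
discount_factor <- function(cycle_index, annual_rate = 0.03, cycle_days = 21) {
  (1 + annual_rate)^(-cycle_index * cycle_days / 365.25)
}

#' Expected one-off adverse-event cost of an arm
#'
#' Sum over the arm's adverse events of incidence x unit treatment cost,
#' applied once at model entry.
#'
#' @param profile Adverse-event profile: named list of
#'   `list(incidence = , cost = dist_spec)`.
#' @return Expected cost, USD.
#' @export
expected_ae_cost <- function(profile) {
  if (!length(profile)) return(0)
  sum(vapply(profile, function(e) e$incidence * e$cost$base, 0))
}

#' Weighted per-cycle drug cost of a treatment mixture
#'
#' Weighted mean of the component per-cycle costs, with weights
#' renormalized to sum to 1 (the published physician's-choice shares
#' 44/40/10/7 sum to 101%).
#'
#' @param weights Positive mixture weights.
#' @param costs Per-cycle costs, same length.
#' @return Weighted per-cycle cost, USD.
#' @export
mix_cycle_cost <- function(weights, costs) {
  if (!length(weights) || length(weights) != length(costs)) {
    stop("weights and costs must be non-empty and of equal length")
  }
  if (any(weights <= 0)) stop("mixture weights must be positive")
  sum(weights / sum(weights) * costs)
}

# Effective per-cycle drug cost of an arm (single drug or mixture).
arm_drug_cycle_cost <- function(arm) {
  mix_cycle_cost(vapply(arm$drug_cost, function(d) d$weight %||% 1, 0),
                 vapply(arm$drug_cost, function(d) d$base, 0))
}

cost_table_sum <- function(scenario, applies) {
  items <- Filter(function(i) identical(i$applies_to, applies), scenario$cost_table)
  if (!length(items)) return(0)
  sum(vapply(items, function(i) i$base, 0))
}

# Per-cycle cost while alive in PFS states (STABLE/REMISSION) includes
# items tagged all_alive or pfs_states; the progressed state includes
# all_alive plus progressed_state therapy.
nonpharma_cycle_cost <- function(scenario) {
  cost_table_sum(scenario, "all_alive")
}

#' Per-cycle cost of occupying a health state
#'
#' STABLE and REMISSION: arm drug cycle cost plus the per-cycle
#' non-pharmaceutical sum; RELAPSE: progressed-state therapy
#' (docetaxel + prednisone) plus the non-pharmaceutical sum; DEATH: 0.
#'
#' @param state One of `cea_states()`.
#' @param arm Arm list from a scenario.
#' @param scenario The `cea_scenario`.
#' @return Cost per cycle, USD.
#' @export
state_cycle_cost <- function(state, arm, scenario) {
  if (!state %in% cea_states()) stop("unknown state: ", state)
  np <- nonpharma_cycle_cost(scenario) + cost_table_sum(scenario, "pfs_states") *
    (state %in% c("STABLE", "REMISSION"))
  switch(state,
    STABLE = ,
    REMISSION = arm_drug_cycle_cost(arm) + np,
    RELAPSE = cost_table_sum(scenario, "progressed_state") + np,
    DEATH = 0)
}

utility_vector <- function(scenario) {
  u <- scenario$utilities
  c(u$stable$base, u$remission$base, u$relapse$base, u$death$base)
}

#' Discounted cost and QALY totals for one arm
#'
#' Accumulates, over the trace, the weighted discounted per-cycle flows:
#' \deqn{cost = oneoff + \sum_k w_k d_k \sum_s occ_{k,s}\, c_s}
#' \deqn{QALY = \sum_k w_k d_k \frac{cycle\_days}{365.25} \sum_s occ_{k,s}\, u_s}
#' where the one-off term is BRCA profiling plus the expected
#' adverse-event cost, `w` the (half-cycle) weights and `d` the discount
#' factors.
#'
#' @param trace A `state_trace` produced under the scenario's settings.
#' @param arm Arm list from the scenario.
#' @param scenario The `cea_scenario`.
#' @return An `arm_result`: list with `total_cost_usd`, `total_qaly` and a
#'   per-category `breakdown` (drug, progressed_therapy, non_pharmaceutical,
#'   one_off_brca, one_off_ae).
#' @export
evaluate_arm <- function(trace, arm, scenario) {
  set <- scenario$settings
  if (abs(trace$cycle_days - set$cycle_days) > 1e-9) {
    stop("trace cycle length does not match scenario settings")
  }
  occ <- trace$occupancy
  n <- nrow(occ) - 1
  wd <- trace$weights * discount_factor(0:n, set$annual_discount_rate, set$cycle_days)

  drug <- arm_drug_cycle_cost(arm)
  np <- nonpharma_cycle_cost(scenario)
  np_pfs <- cost_table_sum(scenario, "pfs_states")
  pd <- cost_table_sum(scenario, "progressed_state")

  pfs_py <- sum(wd * (occ[, 1] + occ[, 2]))   # discounted weighted person-cycles
  rel_py <- sum(wd * occ[, 3])

  breakdown <- c(
    drug = drug * pfs_py,
    progressed_therapy = pd * rel_py,
    non_pharmaceutical = np * (pfs_py + rel_py) + np_pfs * pfs_py,
    one_off_brca = cost_table_sum(scenario, "one_off"),
    one_off_ae = expected_ae_cost(arm$ae_profile)
  )
  qaly <- sum(wd * as.numeric(occ %*% utility_vector(scenario))) *
    set$cycle_days / 365.25

  structure(list(total_cost_usd = sum(breakdown), total_qaly = qaly,
                 breakdown = as.list(breakdown), arm = arm$name %||% ""),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("Arm %s: total cost %.2f USD, %.3f QALYs\n",
              if (nzchar(x$arm)) sQuote(x$arm) else "", x$total_cost_usd,
              x$total_qaly))
  b <- unlist(x$breakdown)
  for (nm in names(b)) cat(sprintf("  %-20s %12.2f\n", nm, b[nm]))
  invisible(x)
}

#' Serialize an arm result as JSON
#'
#' @param x An `arm_result`.
#' @param path Output file.
#' @export
write_arm_result_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Audit helper: reconstruct a per-cycle drug cost from dose and unit price
#'
#' The canonical model inputs are the printed per-cycle costs; this helper
#' reconstructs a cycle cost from a per-unit price, a per-dose prescription
#' (per m2 body-surface area or flat), doses per cycle, and the mean
#' body-surface area (1.67 m2 China, 1.72 m2 US), for auditing the printed
#' values (which do not always equal dose x unit price exactly).
#'
#' @param unit_price_usd Price per dispensing unit.
#' @param units_per_dose Units per administered dose (after any BSA scaling).
#' @param doses_per_cycle Administrations per 21-day cycle.
#' @return Reconstructed cycle cost, USD.
#' @export
dose_based_cycle_cost <- function(unit_price_usd, units_per_dose, doses_per_cycle) {
  unit_price_usd * units_per_dose * doses_per_cycle
}
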