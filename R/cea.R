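# Central model interface: fit the Markov cohort cost-effectiveness model
# to a scenario and expose the results through standard S3 methods.

#' Fit the Markov cohort cost-effectiveness model to a scenario
#'
#' Runs the full deterministic pipeline: derives each arm's per-cycle
#' transition matrix from its trial endpoint summary, advances the cohort
#' trace over the model horizon, values both arms in discounted costs and
#' QALYs, and computes the incremental comparison (ICER, dominance,
#' incremental NMB at the scenario willingness to pay) with the
#' GDP-multiple classification.
#'
#' @param scenario A `cea_scenario` from [read_scenario()] or
#'   [bundled_scenario()].
#' @return A `markov_cea` object: list with `scenario`, per-arm `matrices`,
#'   `traces` and `results`, the `ce` comparison, and `classification`.
#'   Methods: [print.markov_cea()], [summary.markov_cea()],
#'   [coef.markov_cea()], [plot.markov_cea()], [simulate.markov_cea()].
#' @examples
#' fit <- markov_cea(bundled_scenario("china"))
#' fit
#' coef(fit)
#' @export
markov_cea <- function(scenario) {
  if (!inherits(scenario, "cea_scenario")) scenario <- as_cea_scenario(scenario)
  v <- validate_scenario(scenario)
  if (length(v)) stop("invalid scenario:\n  - ", paste(v, collapse = "\n  - "))
  point <- cea_point(scenario)
  icer <- point$ce$icer_usd_per_qaly
  cls <- gdp_classification(icer, scenario$settings$gdp_per_capita %||%
                              scenario$settings$wtp_per_qaly / 3,
                            delta_qaly = point$ce$delta_qaly)
  structure(list(
    scenario = scenario,
    matrices = lapply(point$arms, `[[`, "matrix"),
    traces = lapply(point$arms, `[[`, "trace"),
    results = lapply(point$arms, `[[`, "result"),
    ce = point$ce,
    classification = cls
  ), class = "markov_cea")
}

arm_labels <- function(x) {
  vapply(x$scenario$arms, function(a) a$name %||% "", "")
}

#' @export
print.markov_cea <- function(x, ...) {
  lab <- arm_labels(x)
  cat(sprintf("Markov cohort cost-effectiveness model (%s)\n",
              toupper(x$scenario$country %||% "?")))
  cat(sprintf("%s vs %s, %d cycles of %g days\n\n",
              lab["intervention"], lab["comparator"],
              nrow(x$traces$intervention$occupancy) - 1,
              x$scenario$settings$cycle_days))
  print(x$ce)
  cat(sprintf("GDP-threshold classification: %s\n", x$classification))
  invisible(x)
}

#' Summarize a fitted cost-effectiveness model
#'
#' @param object A `markov_cea` fit.
#' @param ... Unused.
#' @return A `summary.markov_cea` with the arm table, incremental results
#'   and decision statistics.
#' @export
summary.markov_cea <- function(object, ...) {
  lab <- arm_labels(object)
  tab <- ce_summary_table(object$results$intervention,
                          object$results$comparator, object$ce,
                          labels = lab)
  structure(list(table = tab, ce = object$ce,
                 classification = object$classification,
                 country = object$scenario$country %||% NA_character_,
                 wtp = object$scenario$settings$wtp_per_qaly,
                 labels = lab),
            class = "summary.markov_cea")
}

#' @export
print.summary.markov_cea <- function(x, ...) {
  cat(x$table, sep = "\n")
  cat("\n")
  cat(sprintf("Dominance: %s; incremental NMB %.2f USD at WTP %s USD/QALY\n",
              x$ce$dominance, x$ce$inmb_usd, format(x$wtp, big.mark = ",")))
  cat(sprintf("At the GDP-multiple thresholds, '%s' is %s relative to '%s'.\n",
              x$labels["intervention"], gsub("_", " ", x$classification),
              x$labels["comparator"]))
  invisible(x)
}

#' Transition probabilities of a fitted model
#'
#' @param object A `markov_cea` fit.
#' @param ... Unused.
#' @return Named vector of the primitive per-cycle transition
#'   probabilities of both arms.
#' @export
coef.markov_cea <- function(object, ...) {
  out <- c()
  for (a in names(object$matrices)) {
    m <- object$matrices[[a]]
    v <- c(m["STABLE", "REMISSION"], m["REMISSION", "RELAPSE"],
           m["RELAPSE", "DEATH"], m["STABLE", "RELAPSE"],
           m["STABLE", "DEATH"])
    names(v) <- paste(a, c("stable_to_remission", "remission_to_relapse",
                           "relapse_to_death", "stable_to_relapse",
                           "stable_to_death"), sep = ".")
    out <- c(out, v)
  }
  out
}

#' Plot the cohort traces of a fitted model
#'
#' State occupancy over time for both arms (base graphics; one panel per
#' arm).
#'
#' @param x A `markov_cea` fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.markov_cea <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  lab <- arm_labels(x)
  for (a in names(x$traces)) {
    occ <- x$traces[[a]]$occupancy
    graphics::matplot((seq_len(nrow(occ)) - 1) * x$traces[[a]]$cycle_days / 365.25,
                      occ, type = "l", lty = 1, lwd = 2,
                      col = c("forestgreen", "steelblue", "orange", "grey30"),
                      xlab = "years", ylab = "cohort fraction",
                      main = lab[a], ylim = c(0, 1), ...)
    graphics::legend("right", legend = cea_states(), lty = 1, lwd = 2,
                     col = c("forestgreen", "steelblue", "orange", "grey30"),
                     bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Probabilistic sensitivity analysis of a fitted model
#'
#' `simulate()` on a `markov_cea` fit runs the seeded Monte Carlo PSA
#' ([run_psa()]) on the fit's scenario.
#'
#' @param object A `markov_cea` fit.
#' @param nsim Number of Monte Carlo replicates (default 1000).
#' @param seed Root seed (default 1).
#' @param ... Unused.
#' @return A `cea_psa` data frame; see [run_psa()].
#' @export
simulate.markov_cea <- function(object, nsim = 1000, seed = 1, ...) {
  run_psa(object$scenario, n_iter = nsim, seed = seed)
}
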