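# Sensitivity analysis: one-way deterministic sweeps (tornado), seeded
# Monte Carlo probabilistic sensitivity analysis, cost-effectiveness plane
# and acceptability curve.

#' Build a random sampler for a distribution specification
#'
#' Probability / utility parameters use a beta distribution and costs a
#' gamma distribution, each moment-matched to mean = `base` and
#' sd = `(high - low) / 3.92` (the range read as a 95% interval);
#' `triangular` uses mode = `base` on support `[low, high]`; `fixed`
#' returns the base constant.  Beta parameters are clipped to validity
#' when the implied variance is unattainable.
#'
#' @param spec A `dist_spec` (or list with `family`, `base`, `low`, `high`).
#' @return A function `f(n)` drawing `n` values from the current RNG stream.
#' @examples
#' set.seed(1)
#' f <- make_sampler(dist_spec("triangular", 3440.97, 2752.78, 4129.16))
#' range(f(1000))  # within [2752.78, 4129.16]
#' @export
make_sampler <- function(spec) {
  family <- spec$family
  base <- spec$base
  low <- spec$low %||% base
  high <- spec$high %||% base
  if (family == "fixed" || high <= low) {
    return(function(n = 1) rep(base, n))
  }
  s <- (high - low) / 3.92
  switch(family,
    beta = {
      if (base <= 0 || base >= 1) {
        stop("beta sampler requires base in (0, 1), got ", base)
      }
      v <- min(s^2, 0.95 * base * (1 - base))  # clip to a valid beta variance
      nu <- base * (1 - base) / v - 1
      a <- max(base * nu, 1e-8)
      b <- max((1 - base) * nu, 1e-8)
      function(n = 1) stats::rbeta(n, a, b)
    },
    gamma = {
      if (base <= 0) stop("gamma sampler requires base > 0, got ", base)
      shape <- base^2 / s^2
      rate <- base / s^2
      function(n = 1) stats::rgamma(n, shape = shape, rate = rate)
    },
    triangular = {
      if (base < low || base > high) {
        stop("triangular mode must lie within [low, high]")
      }
      function(n = 1) r_triangular(n, low, base, high)
    },
    stop("unknown distribution family: ", family)
  )
}

# Inverse-CDF triangular sampler: mode `mode` on [low, high].
r_triangular <- function(n, low, mode, high) {
  u <- stats::runif(n)
  fc <- (mode - low) / (high - low)
  ifelse(u < fc,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}

#' Uncertain-parameter registry of a scenario
#'
#' Enumerates every tunable scalar the sensitivity analyses vary: the
#' primitive transition probabilities of each arm (printed SA ranges),
#' the three living-state utilities, every drug / cost-table /
#' adverse-event cost item, adverse-event incidences (+-10%), and the
#' annual discount rate (+-10%, deterministic analysis only).
#'
#' @param scenario A `cea_scenario`.
#' @return Data frame with columns `id`, `path` (slash-joined position in
#'   the scenario), `family`, `base`, `low`, `high`, `kind`
#'   (`probability` / `utility` / `cost` / `rate`) and `psa` (sampled in
#'   the probabilistic analysis?).
#' @export
param_registry <- function(scenario) {
  rows <- list()
  add <- function(id, path, family, base, low, high, kind, psa = TRUE) {
    rows[[length(rows) + 1]] <<- data.frame(
      id = id, path = paste(path, collapse = "/"), family = family,
      base = base, low = low, high = high, kind = kind, psa = psa,
      stringsAsFactors = FALSE)
  }
  trans_base <- list(
    stable_to_remission = function(sv) p_stable_remission(sv$rr %||% response_rate(sv$os_months, sv$pfs_months)),
    remission_to_relapse = function(sv) p_remission_relapse(sv$dor_months),
    relapse_to_death = function(sv) p_relapse_death(sv$os_months, sv$pfs_months))
  for (a in names(scenario$arms)) {
    arm <- scenario$arms[[a]]
    for (nm in names(trans_base)) {
      sa <- arm$transition_sa[[nm]]
      base <- trans_base[[nm]](arm$survival)
      add(paste(a, nm, sep = "."),
          c("arms", a, "transition_overrides", nm), "beta", base,
          sa$low %||% (0.9 * base), sa$high %||% min(1.1 * base, 1),
          "probability")
    }
    for (d in names(arm$drug_cost)) {
      dc <- arm$drug_cost[[d]]
      add(paste(a, "drug_cost", d, sep = "."),
          c("arms", a, "drug_cost", d, "base"), dc$family, dc$base,
          dc$low %||% dc$base, dc$high %||% dc$base, "cost")
    }
    for (e in names(arm$ae_profile)) {
      ev <- arm$ae_profile[[e]]
      add(paste(a, "ae", e, "cost", sep = "."),
          c("arms", a, "ae_profile", e, "cost", "base"), ev$cost$family,
          ev$cost$base, ev$cost$low %||% ev$cost$base,
          ev$cost$high %||% ev$cost$base, "cost")
      add(paste(a, "ae", e, "incidence", sep = "."),
          c("arms", a, "ae_profile", e, "incidence"), "beta", ev$incidence,
          0.9 * ev$incidence, min(1.1 * ev$incidence, 1), "probability")
    }
  }
  for (st in c("stable", "remission", "relapse")) {
    u <- scenario$utilities[[st]]
    add(paste("utility", st, sep = "."), c("utilities", st, "base"),
        u$family, u$base, u$low %||% u$base, u$high %||% u$base, "utility")
  }
  for (nm in names(scenario$cost_table)) {
    item <- scenario$cost_table[[nm]]
    add(paste("cost", nm, sep = "."), c("cost_table", nm, "base"),
        item$family, item$base, item$low %||% item$base,
        item$high %||% item$base, "cost")
  }
  r <- scenario$settings$annual_discount_rate
  add("settings.annual_discount_rate", c("settings", "annual_discount_rate"),
      "fixed", r, 0.9 * r, 1.1 * r, "rate", psa = FALSE)
  do.call(rbind, rows)
}

set_scenario_value <- function(scenario, path, value) {
  keys <- strsplit(path, "/", fixed = TRUE)[[1]]
  assign_rec <- function(x, keys) {
    if (is.null(x)) x <- list()
    if (length(keys) == 1L) {
      x[[keys]] <- value
    } else {
      x[[keys[1]]] <- assign_rec(x[[keys[1]]], keys[-1])
    }
    x
  }
  assign_rec(scenario, keys)
}

# Deterministic end-to-end evaluation of a scenario: matrices, traces,
# arm results, incremental comparison.  The workhorse behind markov_cea(),
# the tornado and the PSA.
cea_point <- function(scenario) {
  set <- scenario$settings
  n <- n_cycles(set)
  arms <- lapply(scenario$arms, function(arm) {
    m <- build_matrix(arm$survival, stable_to_death = set$stable_to_death,
                      override = arm$transition_overrides)
    trace <- run_cohort(m, n = n, cycle_days = set$cycle_days,
                        half_cycle = isTRUE(set$half_cycle_correction))
    list(matrix = m, trace = trace,
         result = evaluate_arm(trace, arm, scenario))
  })
  ce <- incremental(arms$intervention$result, arms$comparator$result,
                    wtp = set$wtp_per_qaly)
  list(arms = arms, ce = ce)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full deterministic pipeline with each registry parameter at
#' its low and high bound, everything else at base.  Varied transition
#' probabilities re-enter the matrix as overrides, so their rows are
#' re-completed through the complement entries; a bound that makes the
#' stable row infeasible is recorded as such, never clipped.
#'
#' @param scenario A `cea_scenario`.
#' @param registry Parameter registry (default [param_registry()]).
#' @param statistic Tornado output statistic: `"icer"`, `"inmb"`
#'   (incremental net monetary benefit at the scenario WTP), or `"auto"`
#'   (ICER when the base case is a cost-QALY trade-off, otherwise iNMB,
#'   since negative ICERs are not rankable).
#' @return A `cea_tornado` data frame: `parameter_id`, `low_input`,
#'   `high_input`, `stat_at_low`, `stat_at_high`, `bar_width`, `status`,
#'   sorted by descending bar width; attributes `statistic` and
#'   `base_stat`.
#' @export
one_way_dsa <- function(scenario, registry = NULL,
                        statistic = c("auto", "icer", "inmb")) {
  statistic <- match.arg(statistic)
  if (is.null(registry)) registry <- param_registry(scenario)
  base_point <- cea_point(scenario)
  if (statistic == "auto") {
    statistic <- if (base_point$ce$dominance == "trade_off") "icer" else "inmb"
  }
  stat_of <- function(ce) {
    if (statistic == "icer" && !is.na(ce$icer_usd_per_qaly)) ce$icer_usd_per_qaly
    else ce$inmb_usd
  }
  eval_at <- function(path, value) {
    res <- try(cea_point(set_scenario_value(scenario, path, value)),
               silent = TRUE)
    if (inherits(res, "try-error")) NA_real_ else stat_of(res$ce)
  }
  lo <- mapply(eval_at, registry$path, registry$low)
  hi <- mapply(eval_at, registry$path, registry$high)
  status <- ifelse(is.na(lo) & is.na(hi), "infeasible_both",
            ifelse(is.na(lo), "infeasible_low",
            ifelse(is.na(hi), "infeasible_high", "ok")))
  out <- data.frame(parameter_id = registry$id, low_input = registry$low,
                    high_input = registry$high, stat_at_low = lo,
                    stat_at_high = hi, bar_width = abs(hi - lo),
                    status = status, stringsAsFactors = FALSE)
  out <- out[order(-out$bar_width, out$parameter_id, na.last = TRUE), ]
  rownames(out) <- NULL
  structure(out, class = c("cea_tornado", "data.frame"),
            statistic = statistic, base_stat = stat_of(base_point$ce))
}

#' @export
plot.cea_tornado <- function(x, top = 12, ...) {
  d <- x[x$status == "ok" & x$bar_width > 0, ][seq_len(min(top, sum(x$status == "ok"))), ]
  d <- d[rev(seq_len(nrow(d))), ]
  base <- attr(x, "base_stat")
  op <- graphics::par(mar = c(4, 14, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = range(c(d$stat_at_low, d$stat_at_high, base)),
                 ylim = c(0.5, nrow(d) + 0.5), yaxt = "n",
                 xlab = paste("tornado statistic:", attr(x, "statistic")),
                 ylab = "", ...)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter_id, las = 1,
                 cex.axis = 0.7)
  graphics::rect(pmin(d$stat_at_low, d$stat_at_high), seq_len(nrow(d)) - 0.35,
                 pmax(d$stat_at_low, d$stat_at_high), seq_len(nrow(d)) + 0.35,
                 col = "steelblue")
  graphics::abline(v = base, lty = 2)
  invisible(x)
}

#' Probabilistic sensitivity analysis (seeded Monte Carlo)
#'
#' Each replicate independently redraws every distributional parameter
#' (transition probabilities and utilities from beta, costs from gamma or
#' triangular distributions as specified), rebuilds both transition
#' matrices, reruns the cohort traces and the valuation.  Replicates whose
#' drawn stable row is infeasible are redrawn and counted.  Per-replicate
#' RNG substreams are derived from the root seed, so results do not depend
#' on evaluation order.
#'
#' @param scenario A `cea_scenario`.
#' @param n_iter Number of Monte Carlo replicates (default 1000).
#' @param seed Root seed.
#' @return A `cea_psa` data frame with one row per replicate
#'   (`cost_intervention`, `qaly_intervention`, `cost_comparator`,
#'   `qaly_comparator`) and attributes `seed`, `n_iter`, `redraws`, `wtp`.
#' @export
run_psa <- function(scenario, n_iter = 1000, seed = 1) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  registry <- param_registry(scenario)
  registry <- registry[registry$psa & registry$family != "fixed", ]
  samplers <- lapply(seq_len(nrow(registry)), function(j) {
    make_sampler(list(family = registry$family[j], base = registry$base[j],
                      low = registry$low[j], high = registry$high[j]))
  })
  s2d <- scenario$settings$stable_to_death
  trans_idx <- lapply(names(scenario$arms), function(a) {
    list(tsr = which(registry$id == paste0(a, ".stable_to_remission")),
         trp = which(registry$id == paste0(a, ".remission_to_relapse")))
  })
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n_iter)
  out <- matrix(NA_real_, n_iter, 4,
                dimnames = list(NULL, c("cost_intervention", "qaly_intervention",
                                        "cost_comparator", "qaly_comparator")))
  redraws <- 0L
  for (i in seq_len(n_iter)) {
    set.seed(iter_seeds[i])
    repeat {
      draws <- vapply(samplers, function(f) f(1), 0)
      feasible <- all(vapply(trans_idx, function(ix) {
        4 * draws[ix$trp] + draws[ix$tsr] + s2d <= 1
      }, logical(1)))
      if (feasible) break
      redraws <- redraws + 1L
      if (redraws > 500 + 2 * n_iter) {
        stop("PSA aborted: more than 50% of parameter draws produced an infeasible stable row")
      }
    }
    s_i <- scenario
    for (j in seq_len(nrow(registry))) {
      s_i <- set_scenario_value(s_i, registry$path[j], draws[j])
    }
    point <- cea_point(s_i)
    out[i, ] <- c(point$arms$intervention$result$total_cost_usd,
                  point$arms$intervention$result$total_qaly,
                  point$arms$comparator$result$total_cost_usd,
                  point$arms$comparator$result$total_qaly)
  }
  if (redraws / (redraws + n_iter) > 0.5) {
    stop("PSA aborted: more than 50% of parameter draws were infeasible")
  }
  structure(as.data.frame(out), class = c("cea_psa", "data.frame"),
            seed = seed, n_iter = n_iter, redraws = redraws,
            wtp = scenario$settings$wtp_per_qaly,
            country = scenario$country %||% NA_character_)
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA replicates with positive incremental net monetary
#' benefit at each willingness-to-pay value.
#'
#' @param draws A `cea_psa`.
#' @param wtp_grid Non-empty vector of non-negative WTP values per QALY.
#' @return A `cea_ceac` data frame with columns `wtp` and
#'   `probability_cost_effective`.
#' @export
ceac <- function(draws, wtp_grid) {
  if (!length(wtp_grid) || any(wtp_grid < 0)) {
    stop("wtp_grid must be non-empty and non-negative")
  }
  dq <- draws$qaly_intervention - draws$qaly_comparator
  dc <- draws$cost_intervention - draws$cost_comparator
  p <- vapply(wtp_grid, function(w) mean(w * dq - dc > 0), 0)
  structure(data.frame(wtp = wtp_grid, probability_cost_effective = p),
            class = c("cea_ceac", "data.frame"))
}

#' @export
plot.cea_ceac <- function(x, ...) {
  graphics::plot(x$wtp, x$probability_cost_effective, type = "l",
                 ylim = c(0, 1), xlab = "willingness to pay (USD/QALY)",
                 ylab = "P(intervention cost-effective)", ...)
  invisible(x)
}

#' Cost-effectiveness plane points
#'
#' One (incremental QALY, incremental cost) pair per PSA replicate; the
#' scenario WTP is attached as the threshold-line slope for plotting.
#'
#' @param draws A `cea_psa`.
#' @return A `cea_plane` data frame with `delta_qaly`, `delta_cost`
#'   columns and attribute `wtp_slope`.
#' @export
ce_plane <- function(draws) {
  if (!nrow(draws)) stop("draws must be non-empty")
  structure(data.frame(
    delta_qaly = draws$qaly_intervention - draws$qaly_comparator,
    delta_cost = draws$cost_intervention - draws$cost_comparator),
    class = c("cea_plane", "data.frame"), wtp_slope = attr(draws, "wtp"))
}

#' @export
plot.cea_plane <- function(x, ...) {
  graphics::plot(x$delta_qaly, x$delta_cost, pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.5),
                 xlab = "incremental QALY", ylab = "incremental cost (USD)", ...)
  graphics::abline(0, attr(x, "wtp_slope"), lty = 2)
  graphics::abline(h = 0, v = 0, col = "grey")
  invisible(x)
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("PSA: %d replicates (seed %s, %d infeasible redraws)\n",
              attr(x, "n_iter"), attr(x, "seed"), attr(x, "redraws")))
  dq <- x$qaly_intervention - x$qaly_comparator
  dc <- x$cost_intervention - x$cost_comparator
  cat(sprintf("mean incremental cost %.2f USD, mean incremental QALY %.3f\n",
              mean(dc), mean(dq)))
  w <- attr(x, "wtp")
  cat(sprintf("P(cost-effective at WTP %s): %.3f\n",
              format(w, big.mark = ","), mean(w * dq - dc > 0)))
  invisible(x)
}
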