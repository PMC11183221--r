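# Incremental cost-effectiveness comparison: ICER, dominance, NMB and
# GDP-multiple decision rules.

#' Incremental cost-effectiveness of intervention vs comparator
#'
#' @param intervention,comparator `arm_result` objects (or any lists with
#'   `total_cost_usd` and `total_qaly`) from the same scenario.
#' @param wtp Optional willingness-to-pay per QALY; when given, the
#'   incremental net monetary benefit `wtp * dQALY - dcost` is included.
#' @return A `ce_result`: `delta_cost_usd`, `delta_qaly`,
#'   `icer_usd_per_qaly` (`NA` when `delta_qaly == 0`), `dominance`
#'   (`dominant` / `dominated` / `trade_off` / `equivalent`) and `inmb_usd`.
#'   A dominant strategy (cheaper, more effective) carries a negative,
#'   non-rankable ICER which is reported signed; NMB is the primary
#'   decision statistic in that case.
#' @examples
#' incremental(list(total_cost_usd = 12513.40, total_qaly = 3.06),
#'             list(total_cost_usd = 8786.68, total_qaly = 1.56))
#' @export
incremental <- function(intervention, comparator, wtp = NULL) {
  dc <- intervention$total_cost_usd - comparator$total_cost_usd
  dq <- intervention$total_qaly - comparator$total_qaly
  icer <- if (dq != 0) dc / dq else NA_real_
  dominance <- if (dc < 0 && dq > 0) "dominant"
    else if (dc > 0 && dq < 0) "dominated"
    else if (dc == 0 && dq == 0) "equivalent"
    else "trade_off"
  structure(list(delta_cost_usd = dc, delta_qaly = dq,
                 icer_usd_per_qaly = icer, dominance = dominance,
                 inmb_usd = if (is.null(wtp)) NA_real_ else nmb(dq, dc, wtp),
                 wtp = wtp %||% NA_real_),
            class = "ce_result")
}

#' Net monetary benefit
#'
#' `wtp * qaly - cost`; applied to incremental quantities it gives the
#' incremental NMB, positive iff the intervention is cost-effective at
#' that willingness to pay.
#'
#' @param qaly QALYs (or incremental QALYs).
#' @param cost Cost in USD (or incremental cost).
#' @param wtp Willingness to pay per QALY (>= 0).
#' @return NMB in USD.
#' @export
nmb <- function(qaly, cost, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0")
  wtp * qaly - cost
}

#' GDP-multiple cost-effectiveness classification
#'
#' Chinese pharmacoeconomic-guideline thresholds: ICER below per-capita
#' GDP is cost-effective; between one and three times per-capita GDP is
#' acceptable; above three times is not cost-effective.  A negative ICER
#' arising from a dominant strategy (`delta_qaly > 0`) is cost-effective.
#'
#' @param icer ICER in USD per QALY (may be negative or `NA`).
#' @param gdp_per_capita Per-capita GDP, USD (> 0).
#' @param delta_qaly Optional incremental QALY, used to interpret negative
#'   or undefined ICERs.
#' @return One of `"cost_effective"`, `"acceptable"`,
#'   `"not_cost_effective"`, or `"undefined"` (zero incremental QALY with
#'   no cost saving).
#' @export
gdp_classification <- function(icer, gdp_per_capita, delta_qaly = NULL) {
  if (gdp_per_capita <= 0) stop("gdp_per_capita must be > 0")
  if (is.na(icer)) {
    if (!is.null(delta_qaly) && delta_qaly == 0) return("undefined")
    return("undefined")
  }
  if (icer < 0) {
    if (is.null(delta_qaly) || delta_qaly > 0) return("cost_effective")
    return("not_cost_effective")  # dominated: costs more, loses QALYs
  }
  if (icer < gdp_per_capita) "cost_effective"
  else if (icer <= 3 * gdp_per_capita) "acceptable"
  else "not_cost_effective"
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("Incremental cost:  %12.2f USD\n", x$delta_cost_usd))
  cat(sprintf("Incremental QALY:  %12.2f\n", x$delta_qaly))
  cat(sprintf("ICER:              %12.2f USD/QALY  [%s]\n",
              x$icer_usd_per_qaly, x$dominance))
  if (!is.na(x$inmb_usd)) {
    cat(sprintf("Incremental NMB:   %12.2f USD at WTP %s USD/QALY\n",
                x$inmb_usd, format(x$wtp, big.mark = ",")))
  }
  invisible(x)
}

#' Plain-text incremental summary table
#'
#' Mirrors the column order of published base-case tables: regimen, cost,
#' utility (QALY gain), incremental cost, incremental utility, ICER.
#'
#' @param intervention,comparator `arm_result` objects.
#' @param ce Matching `ce_result` from [incremental()].
#' @param labels Row labels for the two regimens.
#' @return Character vector of table lines, invisibly printed by `cat`.
#' @export
ce_summary_table <- function(intervention, comparator, ce,
                             labels = c("intervention", "comparator")) {
  fmt <- function(x) formatC(x, format = "f", digits = 2, big.mark = ",")
  header <- sprintf("%-18s %14s %10s %14s %12s %14s", "Regimen", "Cost ($)",
                    "QALY", "Incr. cost ($)", "Incr. QALY", "ICER ($/QALY)")
  r1 <- sprintf("%-18s %14s %10s %14s %12s %14s", labels[1],
                fmt(intervention$total_cost_usd), fmt(intervention$total_qaly),
                fmt(ce$delta_cost_usd), fmt(ce$delta_qaly),
                if (is.na(ce$icer_usd_per_qaly)) "-" else fmt(ce$icer_usd_per_qaly))
  r2 <- sprintf("%-18s %14s %10s %14s %12s %14s", labels[2],
                fmt(comparator$total_cost_usd), fmt(comparator$total_qaly),
                "-", "-", "-")
  c(header, r1, r2)
}
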