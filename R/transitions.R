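# Per-cycle transition probabilities from trial endpoint medians.
#
# Median survival endpoints are converted to constant per-cycle transition
# probabilities under an exponential (DEALE-style) assumption: a median
# survival M months implies a per-cycle event probability
# 1 - exp(-DEALE_FACTOR / M) for a 21-day (0.75-month-scale) cycle.

#' Health-state labels of the cohort model
#'
#' Ordered state vector used throughout: `STABLE` (on first-line treatment,
#' pre-response), `REMISSION` (responding), `RELAPSE` (progressed disease)
#' and absorbing `DEATH`.
#'
#' @return Character vector of length four.
#' @export
cea_states <- function() c("STABLE", "REMISSION", "RELAPSE", "DEATH")

# 0.75 * ln 2: cycle-length factor of the DEALE exponential approximation
# (21-day cycle = 0.75 months on the scale of the median endpoints).
DEALE_FACTOR <- 0.75 * log(2)

#' Model response rate from median survival endpoints
#'
#' The modelled response rate is the fraction of overall survival spent
#' beyond progression-free survival: `RR = (OS - PFS) / OS`.
#'
#' @param os_months Median overall survival, months (> 0).
#' @param pfs_months Median progression-free survival, months,
#'   with `pfs_months <= os_months`.
#' @return Response rate in `[0, 1)`.
#' @examples
#' response_rate(24.3, 8.6)  # 0.646 at 3 dp
#' response_rate(6.3, 5.6)   # 0.111 at 3 dp
#' @export
response_rate <- function(os_months, pfs_months) {
  if (any(os_months <= 0)) stop("os_months must be positive")
  if (any(pfs_months <= 0)) stop("pfs_months must be positive")
  if (any(os_months < pfs_months)) {
    stop("os_months must be >= pfs_months: response rate undefined")
  }
  (os_months - pfs_months) / os_months
}

#' Per-cycle probability of relapse from remission
#'
#' `1 - exp(-0.75 ln(2) / DOR)`: duration of response treated as a median
#' under an exponential time-to-relapse.
#'
#' @param dor_months Median duration of response, months (> 0).
#' @return Probability in `(0, 1)`.
#' @export
p_remission_relapse <- function(dor_months) {
  if (any(dor_months <= 0)) stop("dor_months must be positive")
  1 - exp(-DEALE_FACTOR / dor_months)
}

#' Per-cycle probability of death from the relapse state
#'
#' `1 - exp(-0.75 ln(2) / (OS - PFS))`: post-progression survival is the
#' gap between the overall-survival and progression-free-survival medians.
#'
#' @inheritParams response_rate
#' @return Probability in `(0, 1)`.
#' @export
p_relapse_death <- function(os_months, pfs_months) {
  if (any(os_months <= pfs_months)) {
    stop("os_months must exceed pfs_months: relapse-to-death rate undefined")
  }
  1 - exp(-DEALE_FACTOR / (os_months - pfs_months))
}

#' Per-cycle probability of remission from the stable state
#'
#' `1 - exp(-RR / 3)`.
#'
#' @param rr Response rate in `[0, 1]`.
#' @return Probability in `[0, 1)`.
#' @export
p_stable_remission <- function(rr) {
  if (any(rr < 0 | rr > 1)) stop("rr must lie in [0, 1]")
  1 - exp(-rr / 3)
}

#' Build the per-cycle transition matrix for one arm
#'
#' Derives the full 4x4 row-stochastic matrix over
#' (STABLE, REMISSION, RELAPSE, DEATH) from one arm's endpoint summary.
#' The three primitive probabilities are computed unrounded by
#' [p_stable_remission()], [p_remission_relapse()] and [p_relapse_death()];
#' the remaining entries are complements:
#' stable->relapse = `relapse_multiplier` x remission->relapse,
#' stable->stable, remission->remission and relapse->relapse close their
#' rows, and DEATH is absorbing.
#'
#' @param survival List with `os_months`, `pfs_months`, `dor_months` and
#'   optionally `rr` (computed from OS/PFS when absent).
#' @param stable_to_death Optional per-cycle stable->death probability
#'   (default 0; the base parameterization defines none).
#' @param relapse_multiplier Multiplier linking stable->relapse to
#'   remission->relapse (default 4, as parameterized).
#' @param override Optional named list overriding any of the primitive
#'   probabilities `stable_to_remission`, `remission_to_relapse`,
#'   `relapse_to_death` (used by sensitivity analyses).
#' @return A `transition_matrix`: 4x4 numeric matrix with state dimnames,
#'   the source summary attached as attribute `survival`.
#' @examples
#' build_matrix(list(os_months = 6.3, pfs_months = 5.6, dor_months = 3.1))
#' @export
build_matrix <- function(survival, stable_to_death = 0, relapse_multiplier = 4,
                         override = NULL) {
  if (stable_to_death < 0 || stable_to_death >= 1) {
    stop("stable_to_death must lie in [0, 1)")
  }
  rr <- survival$rr
  if (is.null(rr)) rr <- response_rate(survival$os_months, survival$pfs_months)
  tsr <- p_stable_remission(rr)
  trp <- p_remission_relapse(survival$dor_months)
  tpd <- p_relapse_death(survival$os_months, survival$pfs_months)
  if (!is.null(override)) {
    if (!is.null(override$stable_to_remission)) tsr <- override$stable_to_remission
    if (!is.null(override$remission_to_relapse)) trp <- override$remission_to_relapse
    if (!is.null(override$relapse_to_death)) tpd <- override$relapse_to_death
  }
  tsp <- relapse_multiplier * trp
  leak <- tsp + tsr + stable_to_death
  if (leak > 1) {
    stop(sprintf(paste0(
      "infeasible stable row: stable->relapse (%.4f) + stable->remission ",
      "(%.4f) + stable->death (%.4f) = %.4f > 1"),
      tsp, tsr, stable_to_death, leak))
  }
  if (min(tsr, trp, tpd) < 0 || max(tsr, trp, tpd) > 1) {
    stop("transition probabilities must lie in [0, 1]")
  }
  m <- rbind(
    c(1 - leak, tsr, tsp, stable_to_death),
    c(0, 1 - trp, trp, 0),
    c(0, 0, 1 - tpd, tpd),
    c(0, 0, 0, 1)
  )
  dimnames(m) <- list(cea_states(), cea_states())
  structure(m, class = c("transition_matrix", "matrix", "array"),
            survival = survival)
}

#' @export
print.transition_matrix <- function(x, digits = 4, ...) {
  cat("Per-cycle transition matrix (rows: from, columns: to)\n")
  print(round(unclass(x)[, , drop = FALSE], digits), ...)
  sv <- attr(x, "survival")
  if (!is.null(sv)) {
    cat(sprintf("Derived from OS %.1f / PFS %.1f / DOR %.1f months\n",
                sv$os_months, sv$pfs_months, sv$dor_months))
  }
  invisible(x)
}

#' Write a transition matrix as CSV
#'
#' @param x A `transition_matrix`.
#' @param path Output file; the header row names the four states.
#' @export
write_matrix_csv <- function(x, path) {
  df <- data.frame(from_state = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
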