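# Discrete-time Markov cohort trace.

#' Number of model cycles over the horizon
#'
#' `round(horizon_years * 365.25 / cycle_days)`: 87 cycles for the default
#' 5-year horizon of 21-day cycles.
#'
#' @param settings Model settings list with `horizon_years` and `cycle_days`.
#' @return Integer cycle count.
#' @export
n_cycles <- function(settings) {
  as.integer(round(settings$horizon_years * 365.25 / settings$cycle_days))
}

#' Accumulation weights for the cohort trace
#'
#' All-ones, or the trapezoidal half-cycle correction (0.5 at the first and
#' last rows) approximating mid-cycle transitions.
#'
#' @param n Number of cycles (>= 1).
#' @param half_cycle Apply the half-cycle correction?
#' @return Numeric vector of length `n + 1`.
#' @export
cycle_weights <- function(n, half_cycle = TRUE) {
  if (n < 1) stop("n must be >= 1")
  w <- rep(1, n + 1)
  if (half_cycle) w[c(1, n + 1)] <- 0.5
  w
}

#' Run the Markov cohort trace
#'
#' Advances the cohort occupancy by iterated vector-matrix products:
#' `occupancy[k] = init %*% matrix^k` for `k = 0..n`.
#'
#' @param matrix A `transition_matrix` (or any 4x4 row-stochastic matrix).
#' @param init Initial occupancy over (STABLE, REMISSION, RELAPSE, DEATH);
#'   must sum to 1.  Default: the whole cohort starts STABLE.
#' @param n Number of cycles.
#' @param cycle_days Cycle length in days (carried for downstream
#'   discounting and QALY scaling).
#' @param half_cycle Apply the trapezoidal half-cycle correction weights?
#' @return A `state_trace`: list with `occupancy` ((n+1) x 4 matrix, row 0 =
#'   initial distribution), `cycle_days` and `weights`.
#' @examples
#' m <- build_matrix(list(os_months = 6.3, pfs_months = 5.6, dor_months = 3.1))
#' tr <- run_cohort(m, n = 10)
#' rowSums(tr$occupancy)  # all 1
#' @export
run_cohort <- function(matrix, init = c(1, 0, 0, 0), n,
                       cycle_days = 21, half_cycle = TRUE) {
  if (n < 1) stop("n must be >= 1")
  if (abs(sum(init) - 1) > 1e-9) stop("init must sum to 1")
  P <- unclass(matrix)
  occ <- base::matrix(0, nrow = n + 1, ncol = 4,
                      dimnames = list(0:n, cea_states()))
  v <- as.numeric(init)
  occ[1, ] <- v
  for (k in seq_len(n)) {
    v <- as.numeric(v %*% P)
    occ[k + 1, ] <- v
  }
  structure(list(occupancy = occ, cycle_days = cycle_days,
                 weights = cycle_weights(n, half_cycle)),
            class = "state_trace")
}

#' @export
print.state_trace <- function(x, ...) {
  n <- nrow(x$occupancy) - 1
  cat(sprintf("Markov cohort trace: %d cycles of %g days\n", n, x$cycle_days))
  cat("Terminal occupancy:\n")
  print(round(x$occupancy[n + 1, ], 4))
  invisible(x)
}

#' Export a cohort trace as CSV
#'
#' Columns: cycle index, days elapsed, and the four state occupancies.
#'
#' @param trace A `state_trace`.
#' @param path Output file.
#' @export
write_trace_csv <- function(trace, path) {
  n <- nrow(trace$occupancy) - 1
  df <- data.frame(cycle = 0:n, days = (0:n) * trace$cycle_days,
                   trace$occupancy, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
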