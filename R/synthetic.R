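# Synthetic inputs and individual-level microsimulation: endpoint
# summaries with the statistical structure the analysis assumes, patient
# trajectories multinomially sampled from a known transition matrix, and
# maximum-likelihood recovery of that matrix — the pipeline's principal
# parameter-recovery self-test.

#' Generate a random feasible survival summary
#'
#' Draws PFS uniformly on [1, 24] months, OS as PFS times a factor on
#' (1.05, 5], DOR uniformly on [1, 12] months, and sets the response rate
#' by `(OS - PFS) / OS`; redraws until the implied transition matrix is
#' feasible (short DOR values can push stable->relapse = 4 x
#' remission->relapse above 1).  The ranges bracket the observed trial
#' endpoints (PFS 5.6-8.6, OS 6.3-24.3, DOR 3.1-5.4 months) with margin so
#' generated fixtures stress the feasibility boundary.
#'
#' @param stable_to_death Stable->death probability the feasibility check
#'   must accommodate (default 0).
#' @return A survival summary list (`rr`, `os_months`, `pfs_months`,
#'   `dor_months`) that passes [build_matrix()].
#' @export
gen_survival_summary <- function(stable_to_death = 0) {
  repeat {
    pfs <- stats::runif(1, 1, 24)
    os <- pfs * stats::runif(1, 1.05, 5)
    dor <- stats::runif(1, 1, 12)
    sv <- list(rr = response_rate(os, pfs), os_months = os,
               pfs_months = pfs, dor_months = dor)
    ok <- try(build_matrix(sv, stable_to_death = stable_to_death),
              silent = TRUE)
    if (!inherits(ok, "try-error")) return(sv)
  }
}

#' Microsimulate patient trajectories
#'
#' Every patient starts STABLE and steps through per-row multinomial
#' draws from the transition matrix; transitions are aggregated over
#' patients and cycles into a 4x4 count table (patients are exchangeable,
#' so the counts are drawn state-wise with [stats::rmultinom()]).
#'
#' @param matrix A `transition_matrix`.
#' @param n_patients Cohort size.
#' @param n_cycles Number of cycles to simulate.
#' @return A `transition_counts` 4x4 integer matrix; row totals equal the
#'   person-cycles at risk in each state.
#' @export
simulate_patients <- function(matrix, n_patients, n_cycles) {
  if (n_patients < 1 || n_cycles < 1) stop("n_patients and n_cycles must be >= 1")
  P <- unclass(matrix)
  counts <- base::matrix(0L, 4, 4, dimnames = list(cea_states(), cea_states()))
  state_n <- c(n_patients, 0L, 0L, 0L)
  for (k in seq_len(n_cycles)) {
    nxt <- integer(4)
    for (s in 1:4) {
      if (state_n[s] == 0L) next
      moved <- as.integer(stats::rmultinom(1, state_n[s], P[s, ]))
      counts[s, ] <- counts[s, ] + moved
      nxt <- nxt + moved
    }
    state_n <- nxt
  }
  structure(counts, class = c("transition_counts", "matrix", "array"))
}

#' Maximum-likelihood transition matrix from transition counts
#'
#' Row-wise estimate `count[i, j] / rowtotal[i]`; structural zeros are
#' preserved (unvisited transitions stay 0).  An empty non-absorbing row
#' is a domain error; an unvisited DEATH row defaults to its absorbing
#' value.
#'
#' @param counts A `transition_counts` matrix from [simulate_patients()].
#' @return A row-stochastic `transition_matrix` (no `survival` attribute).
#' @export
estimate_matrix <- function(counts) {
  m <- unclass(counts) * 1.0
  totals <- rowSums(m)
  for (s in 1:4) {
    if (totals[s] > 0) {
      m[s, ] <- m[s, ] / totals[s]
    } else if (s == 4L) {
      m[s, ] <- c(0, 0, 0, 1)  # absorbing state never observed
    } else {
      stop("no observed person-cycles in non-absorbing state ", cea_states()[s])
    }
  }
  dimnames(m) <- list(cea_states(), cea_states())
  structure(m, class = c("transition_matrix", "matrix", "array"),
            survival = NULL)
}

#' Perturb a cost table for robustness fixtures
#'
#' Multiplies each item's base (and rescales its range) by an independent
#' positive lognormal factor with mean 1 and standard deviation `rel_sd`;
#' `rel_sd = 0` is the identity.
#'
#' @param cost_table Named list of cost items (as in a scenario).
#' @param rel_sd Relative standard deviation of the perturbation (>= 0).
#' @return Perturbed cost table of the same shape.
#' @export
perturb_cost_table <- function(cost_table, rel_sd) {
  if (rel_sd < 0) stop("rel_sd must be >= 0")
  lapply(cost_table, function(item) {
    f <- if (rel_sd == 0) 1 else {
      sdlog <- sqrt(log(1 + rel_sd^2))
      stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    for (fld in intersect(c("base", "low", "high"), names(item))) {
      item[[fld]] <- item[[fld]] * f
    }
    item
  })
}
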