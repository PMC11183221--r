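# Scenario container: country-labelled bundle of two treatment arms,
# cost tables, health-state utilities, adverse-event profiles and model
# settings, serialized as YAML.  Bundled fixtures transcribe the published
# China and US parameter tables cell by cell.

DIST_FAMILIES <- c("beta", "gamma", "triangular", "fixed")
APPLIES_TO <- c("all_alive", "pfs_states", "progressed_state", "one_off")
AE_EVENTS <- c("anaemia", "neutropenia", "fatigue", "back_pain", "nausea")

#' Distribution specification for an uncertain parameter
#'
#' @param family One of `"beta"`, `"gamma"`, `"triangular"`, `"fixed"`.
#' @param base Point (base-case) value; also the mean targeted by the
#'   moment-matched beta/gamma samplers.
#' @param low,high Sensitivity-analysis range, `low <= base <= high`
#'   (ignored for `"fixed"`).
#' @return A list of class `dist_spec`.
#' @export
dist_spec <- function(family, base, low = base, high = base) {
  family <- match.arg(family, DIST_FAMILIES)
  structure(list(family = family, base = base, low = low, high = high),
            class = "dist_spec")
}

default_settings <- function() {
  list(cycle_days = 21, horizon_years = 5, annual_discount_rate = 0.03,
       half_cycle_correction = TRUE, stable_to_death = 0)
}

#' Read a scenario from a YAML file
#'
#' Parses and validates a scenario configuration.  See the bundled
#' `china.yaml` / `us.yaml` (under `inst/extdata`) for the documented
#' schema: `country`, `settings`, `utilities`, two `arms`
#' (`intervention`, `comparator`) and a `cost_table`.
#'
#' @param path Path to a YAML scenario file.
#' @return A validated `cea_scenario` object.
#' @seealso [validate_scenario()], [bundled_scenario()], [write_scenario()]
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  s <- as_cea_scenario(yaml::read_yaml(path))
  v <- validate_scenario(s)
  if (length(v)) {
    stop("invalid scenario '", path, "':\n  - ", paste(v, collapse = "\n  - "))
  }
  s
}

#' Write a scenario to a YAML file
#'
#' Inverse of [read_scenario()]: `read_scenario(write_scenario(s, f))`
#' reproduces `s`.
#'
#' @param s A `cea_scenario`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(s, path) {
  yaml::write_yaml(strip_classes(s), path, precision = 15)
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

as_cea_scenario <- function(x) {
  if (!is.list(x)) stop("scenario must parse to a mapping")
  x$settings <- utils::modifyList(default_settings(),
                                  if (is.list(x$settings)) x$settings else list())
  for (a in names(x$arms)) {
    sv <- x$arms[[a]]$survival
    if (is.list(sv) && is.null(sv$rr) &&
        is.numeric(sv$os_months) && is.numeric(sv$pfs_months) &&
        sv$os_months >= sv$pfs_months && sv$os_months > 0) {
      x$arms[[a]]$survival$rr <- response_rate(sv$os_months, sv$pfs_months)
    }
  }
  class(x) <- "cea_scenario"
  x
}

check_dist <- function(spec, where, msgs, prob = FALSE) {
  req <- c("family", "base")
  miss <- setdiff(req, names(spec))
  if (length(miss)) {
    return(c(msgs, sprintf("%s: missing key(s) %s", where,
                           paste(miss, collapse = ", "))))
  }
  if (!spec$family %in% DIST_FAMILIES) {
    return(c(msgs, sprintf("%s: unknown distribution family '%s'",
                           where, spec$family)))
  }
  if (spec$family == "fixed") return(msgs)  # fixed ignores low/high
  low <- if (is.null(spec$low)) spec$base else spec$low
  high <- if (is.null(spec$high)) spec$base else spec$high
  if (!(low <= spec$base && spec$base <= high)) {
    msgs <- c(msgs, sprintf("%s: base %s outside [low, high] = [%s, %s]",
                            where, spec$base, low, high))
  }
  if (spec$family == "beta" && (low < 0 || high > 1)) {
    msgs <- c(msgs, sprintf("%s: beta range [%s, %s] outside [0, 1]",
                            where, low, high))
  }
  if (prob && (spec$base < 0 || spec$base > 1)) {
    msgs <- c(msgs, sprintf("%s: probability/utility base %s outside [0, 1]",
                            where, spec$base))
  }
  msgs
}

#' Validate a scenario
#'
#' Checks every type invariant (survival ordering, distribution ranges,
#' utilities in `[0, 1]` with death fixed at 0, non-negative costs,
#' mixture weights, settings bounds) and reports, rather than throws.
#'
#' @param s A `cea_scenario` (or plain list in the scenario schema).
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_scenario <- function(s) {
  msgs <- character()
  if (!inherits(s, "cea_scenario")) s <- try(as_cea_scenario(s), silent = TRUE)
  if (inherits(s, "try-error")) return("scenario is not a mapping")

  set <- s$settings
  if (!is.numeric(set$cycle_days) || set$cycle_days <= 0) {
    msgs <- c(msgs, "ModelSettings: cycle_days must be > 0")
  }
  if (!is.numeric(set$horizon_years) || set$horizon_years <= 0) {
    msgs <- c(msgs, "ModelSettings: horizon_years must be > 0")
  }
  if (!is.numeric(set$annual_discount_rate) ||
      set$annual_discount_rate < 0 || set$annual_discount_rate >= 1) {
    msgs <- c(msgs, "ModelSettings: annual_discount_rate must lie in [0, 1)")
  }
  if (is.null(set$wtp_per_qaly) || !is.numeric(set$wtp_per_qaly) ||
      set$wtp_per_qaly <= 0) {
    msgs <- c(msgs, "ModelSettings: wtp_per_qaly must be > 0")
  }
  if (!is.numeric(set$stable_to_death) || set$stable_to_death < 0 ||
      set$stable_to_death >= 1) {
    msgs <- c(msgs, "ModelSettings: stable_to_death must lie in [0, 1)")
  }

  if (!identical(sort(names(s$arms)), c("comparator", "intervention"))) {
    msgs <- c(msgs, "Scenario: exactly two arms named 'intervention' and 'comparator' required")
  }
  for (a in names(s$arms)) {
    arm <- s$arms[[a]]
    sv <- arm$survival
    where <- sprintf("SurvivalSummary (%s)", a)
    if (!is.list(sv)) {
      msgs <- c(msgs, paste0(where, ": missing"))
      next
    }
    num_ok <- vapply(c("os_months", "pfs_months", "dor_months"), function(f) {
      is.numeric(sv[[f]]) && is.finite(sv[[f]]) && sv[[f]] > 0
    }, logical(1))
    if (!all(num_ok)) {
      msgs <- c(msgs, paste0(where, ": os_months, pfs_months, dor_months must be finite and positive"))
    } else if (sv$os_months <= sv$pfs_months) {
      msgs <- c(msgs, paste0(where, ": os_months must exceed pfs_months (relapse-to-death rate undefined)"))
    }
    if (!is.null(sv$rr) && (!is.numeric(sv$rr) || sv$rr < 0 || sv$rr > 1)) {
      msgs <- c(msgs, paste0(where, ": rr must lie in [0, 1]"))
    }
    if (is.list(arm$drug_cost) && length(arm$drug_cost)) {
      w <- vapply(arm$drug_cost, function(d) d$weight %||% 1, 0)
      if (any(w <= 0)) {
        msgs <- c(msgs, sprintf("Arm (%s): mixture weights must be positive", a))
      }
      for (d in names(arm$drug_cost)) {
        msgs <- check_dist(arm$drug_cost[[d]],
                           sprintf("CostItem (%s drug %s)", a, d), msgs)
      }
    } else {
      msgs <- c(msgs, sprintf("Arm (%s): missing key drug_cost", a))
    }
    if (is.list(arm$ae_profile)) {
      for (e in names(arm$ae_profile)) {
        ev <- arm$ae_profile[[e]]
        if (!is.numeric(ev$incidence) || ev$incidence < 0 || ev$incidence > 1) {
          msgs <- c(msgs, sprintf("AdverseEventProfile (%s, %s): incidence must lie in [0, 1]", a, e))
        }
        msgs <- check_dist(ev$cost, sprintf("AdverseEventProfile (%s, %s) cost", a, e), msgs)
      }
    } else {
      msgs <- c(msgs, sprintf("Arm (%s): missing key ae_profile", a))
    }
  }

  u <- s$utilities
  for (st in c("stable", "remission", "relapse", "death")) {
    if (is.null(u[[st]])) {
      msgs <- c(msgs, sprintf("UtilitySet: missing key %s", st))
    } else {
      msgs <- check_dist(u[[st]], sprintf("UtilitySet (%s)", st), msgs, prob = TRUE)
    }
  }
  if (!is.null(u$death$base) && u$death$base != 0) {
    msgs <- c(msgs, "UtilitySet: death utility must equal 0")
  }

  if (!is.list(s$cost_table) || !length(s$cost_table)) {
    msgs <- c(msgs, "Scenario: missing key cost_table")
  } else {
    for (nm in names(s$cost_table)) {
      item <- s$cost_table[[nm]]
      where <- sprintf("CostItem (%s)", nm)
      if (is.null(item$applies_to) || !item$applies_to %in% APPLIES_TO) {
        msgs <- c(msgs, sprintf("%s: applies_to must be one of %s", where,
                                paste(APPLIES_TO, collapse = ", ")))
      }
      msgs <- check_dist(item, where, msgs)
      if (is.numeric(item$base) && item$base < 0) {
        msgs <- c(msgs, paste0(where, ": per-cycle cost must be >= 0"))
      }
    }
    need <- c("progressed_state", "one_off")
    have <- vapply(s$cost_table, function(i) i$applies_to %||% "", "")
    for (ap in need) {
      if (!ap %in% have) {
        msgs <- c(msgs, sprintf("Scenario: cost_table has no %s item", ap))
      }
    }
  }
  msgs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundled country scenarios
#'
#' Returns the packaged China or US scenario, a cell-by-cell transcription
#' of the published parameter, cost and adverse-event tables for the
#' talazoparib vs physician's-choice chemotherapy comparison.
#'
#' @param country `"china"` or `"us"`.
#' @return A validated `cea_scenario`.
#' @examples
#' ch <- bundled_scenario("china")
#' ch$utilities$remission$base  # 0.85
#' @export
bundled_scenario <- function(country = c("china", "us")) {
  country <- match.arg(country)
  read_scenario(system.file("extdata", paste0(country, ".yaml"),
                            package = "markovcea", mustWork = TRUE))
}

#' @export
print.cea_scenario <- function(x, ...) {
  cat(sprintf("Cost-effectiveness scenario: %s\n", toupper(x$country %||% "?")))
  for (a in names(x$arms)) {
    arm <- x$arms[[a]]
    sv <- arm$survival
    cat(sprintf("  %s arm '%s': OS %.1f, PFS %.1f, DOR %.1f months; drug cost %.2f USD/cycle\n",
                a, arm$name %||% a, sv$os_months, sv$pfs_months, sv$dor_months,
                arm_drug_cycle_cost(arm)))
  }
  set <- x$settings
  cat(sprintf("  %g-day cycles over %g years, discount %.1f%%/yr, WTP %s USD/QALY\n",
              set$cycle_days, set$horizon_years,
              100 * set$annual_discount_rate,
              format(set$wtp_per_qaly, big.mark = ",")))
  invisible(x)
}
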