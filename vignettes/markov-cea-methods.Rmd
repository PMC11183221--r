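---
title: "Methods: the Markov cohort cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Markov cohort cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovcea)
```

## The decision problem

Talazoparib, a PARP inhibitor, extends progression-free survival in
germline BRCA1/2-mutated, HER2-negative advanced breast cancer relative
to physician's-choice chemotherapy (capecitabine, eribulin, gemcitabine
or vinorelbine). Whether that benefit is worth its price depends on the
payer: this package evaluates the comparison from the Chinese and US
healthcare perspectives with a four-state Markov cohort model, the
standard device for chronic-disease cost-effectiveness when only summary
trial endpoints are available.

States are **STABLE** (on first-line treatment, no response yet),
**REMISSION** (responding), **RELAPSE** (progressed, on salvage
docetaxel + prednisone) and absorbing **DEATH**. The whole cohort starts
in STABLE: trial patients enter on treatment before any response is
observed, and the source material states no other initial distribution.

## Transition probabilities from endpoint medians

No patient-level survival data are used — only the arm-level medians
*OS*, *PFS* and *DOR* (months). Each median is converted to a constant
per-cycle event probability under an exponential survival assumption
(the DEALE approach): a median of $M$ months gives per-cycle probability
$1 - \exp(-0.75\ln 2/M)$ for the 21-day (0.75-month) cycle, the factor
$0.75\ln 2$ being the exported constant behind `p_remission_relapse()`
and `p_relapse_death()`. The response rate is modelled, not taken from
the trial's objective response rate: $RR = (OS - PFS)/OS$, the fraction
of survival spent beyond progression-free time. Stable patients relapse
four times as fast as remitting ones ($P_{SD\to PD} = 4 P_{RE\to PD}$, a
multiplier kept configurable in `build_matrix()` for sensitivity work).
Remaining probability mass stays in place, so every row closes to 1 by
construction; death is absorbing; remission never returns to stable.

Two numerical policies matter here:

* **Unrounded internals.** All downstream computation uses full-precision
  probabilities. The printed 3-decimal table values are renderings, and
  they occasionally truncate rather than round (0.193 for 0.1937...);
  tests compare at 3 decimals for the standard-therapy arm and within
  ±0.001 for the talazoparib arm.
* **Feasibility is an error, not a clip.** Small *DOR* values push
  $4P_{RE\to PD} + P_{SD\to RE}$ above 1 (at *DOR* = 1 month the first
  term alone is ≈ 1.62); `build_matrix()` refuses with a message naming
  the offending sum. Sensitivity analyses record such bounds as
  infeasible instead of silently truncating.

## Cohort trace and valuation

`run_cohort()` advances the occupancy vector by iterated vector–matrix
products (exact and auditable; an independent matrix-power oracle is a
test, not the engine). The horizon is `round(horizon_years × 365.25 /
cycle_days)` cycles — 87 for 5 years of 21-day cycles. The source
material elsewhere mentions a one-month cycle; `cycle_days` is a setting
(30.4375 days gives 60 cycles) rather than a second code path.

Valuation (`evaluate_arm()`) accumulates, per cycle $k$ with trapezoidal
half-cycle weights $w_k$ (0.5 at the first and last rows) and discount
$d_k = (1+r)^{-k\,\mathrm{cycle\_days}/365.25}$:

$$\mathrm{cost} = \mathrm{oneoff} + \sum_k w_k d_k \sum_s \mathrm{occ}_{k,s}\, c_s,
\qquad
\mathrm{QALY} = \sum_k w_k d_k \tfrac{\mathrm{cycle\_days}}{365.25} \sum_s \mathrm{occ}_{k,s}\, u_s.$$

Costing conventions (all 2022 USD):

* STABLE and REMISSION pay the arm's per-cycle drug cost — for the
  chemotherapy arm a mixture cost, the printed 44/40/10/7 % shares
  renormalized by their 1.01 total — plus the non-pharmaceutical
  per-cycle items (laboratory tests, CT, nursing, follow-up; bone
  imaging in the US table).
* RELAPSE stops the assigned drug and pays docetaxel + prednisone (the
  only progressed-state medications in the cost tables) plus the same
  non-pharmaceutical items.
* BRCA1/2 profiling and the expected adverse-event cost
  ($\sum_e \mathrm{incidence}_e \times \mathrm{cost}_e$ over the five
  profiled events: anaemia, neutropenia, fatigue, back pain, nausea) are
  one-off, undiscounted charges at entry — the source gives no AE timing.
* Nothing is charged in DEATH and no terminal-care cost exists; utilities
  map STABLE→0.74 (the "no recurrence, chemotherapy period" value, since
  patients are on treatment throughout), REMISSION→0.85, RELAPSE→0.5,
  DEATH→0. The two unused printed utilities are retained in the fixtures
  as alternates.

## Decision statistics

`incremental()` reports Δcost, ΔQALY, ICER (undefined at ΔQALY = 0) and
dominance; a dominant strategy's negative ICER is reported signed but is
not rankable, so incremental NMB at the scenario willingness to pay is
the primary decision statistic. GDP-multiple classification uses strict
"lower than per-capita GDP" for the best class, so boundary ties fall to
the less favorable side. The fixtures set WTP per QALY at 3× per-capita
GDP ($38,223 China, $229,200 US); the source frames these per month
(3185 and 19,100 $/month), which is the same threshold expressed on a
monthly grid — the monthly figures are kept as metadata only.

## Sensitivity analyses

**One-way (tornado), `one_way_dsa()`.** Every registry parameter — the
six primitive transition probabilities (printed SA ranges), three
utilities, every cost item, AE incidences (±10 %), the discount rate
(±10 %) — is set to its low and high bound with everything else at base,
and the full pipeline reruns. Varied transition probabilities re-enter
as overrides so their rows re-close through the complements. The output
statistic is the ICER when the base case is an ordinary cost–QALY
trade-off and the incremental NMB otherwise, because negative ICERs make
raw-ICER tornados unreadable.

**Probabilistic, `run_psa()`.** Each of the (default) 1000 replicates
redraws every distributional parameter: probabilities and utilities from
beta, costs from gamma (or triangular where the tables say so)
distributions. The tables print a point value and a range but no
distribution parameters, so samplers are moment-matched to mean = base
and sd = (high − low)/3.92, reading the range as a central 95 %
interval; beta parameters are clipped to validity when the implied
variance is unattainable. Replicates with an infeasible stable row are
redrawn and counted, and the run aborts if the infeasible fraction
exceeds half. Per-replicate RNG substreams derive from the root seed, so
results are independent of evaluation order and bit-reproducible.
`ceac()` is the fraction of replicates with positive incremental NMB at
each WTP; `ce_plane()` exports the scatter. The discount rate stays at
base in the PSA (it is a policy choice, not a sampling uncertainty) but
is varied in the tornado.

## Synthetic data and self-tests

The microsimulation module is first-class, tested code, not a fixture:
`gen_survival_summary()` draws endpoint summaries (PFS ∈ [1, 24] months,
OS/PFS ∈ (1.05, 5], DOR ∈ [1, 12]) bracketing the observed trial values
with margin so short-DOR draws exercise the feasibility error path;
`simulate_patients()` steps patients by per-row multinomial draws; and
`estimate_matrix()` recovers the generating matrix by row-wise maximum
likelihood. The pipeline's principal self-test chains these: generate →
build matrix → microsimulate 10,000 patients for 40 cycles → re-estimate
→ agree with the truth within ±0.01 (the multinomial standard error at
that size is below 0.006). What the generator deliberately does not
emulate: patient-level survival curves (the model consumes only
medians), correlation between endpoints, and time-varying hazards —
passing tests therefore validate the arithmetic of the pipeline, not the
exponential approximation's fit to any real trial.

Problem sizes used by the test suite — 1000 PSA replicates, 1000 random
matrices for the conservation properties, 10,000 microsimulated
patients, full 87-cycle traces — are the model's own natural scales and
run in well under a minute each.

## Reproduction boundaries and known limitations

* The derived transition probabilities, the incremental worked examples
  (Δcost $3726.72, ICER $2484.48/QALY in China; Δcost −$10,223.43, ICER
  −$6815.62/QALY, dominant, in the US from the printed arm totals), and
  all engine-level properties reproduce exactly and are asserted in the
  test suite.
* The published **arm-level totals** (China $12,513.40 / $8786.68 with
  3.06 / 1.56 QALYs; US $30,987.66 / $41,211.09) are **not** reproducible
  from the printed per-cycle inputs under any documented setting
  combination (discount 3 % or 5 %, half-cycle on or off, 21-day or
  monthly cycles). Recomputed from the printed tables, the China totals
  are ≈ $53,230 / $5648 and 1.02 / 0.12 QALYs: the printed transition
  matrix keeps the talazoparib cohort in the relapse state for ~28
  discounted cycles of salvage-therapy and care costs, which dominates
  cost accrual, while the comparator cohort is almost fully absorbed by
  death within a year (under 10^-3 alive at cycle 87), capping its
  QALYs far below 1.56. The totals are therefore shipped as reference
  inputs (`reference_results`) for the incremental worked examples, not
  asserted as valuation outputs.
* Two downstream published results inherit that gap and the
  corresponding acceptance tests document it by failing: the China CEAC
  at the national threshold (published 96 %; recomputed ≈ 0.1 %, since
  the recomputed ICER sits above the threshold, and the US value 95.6 %
  against a ≥ 99 % check), and the tornado ranking (published: the four
  relapse→death and stable→death probabilities widest; recomputed: the
  relapse utility and the talazoparib/docetaxel costs lead, and no
  stable→death parameter exists in the printed transition table — it is
  exposed as the optional `stable_to_death` setting, default 0).
* Published terminal-state percentages for the talazoparib arm sum to
  107.2 % and cannot arise from any row-stochastic trace; they are
  excluded from testing.
* Textual ambiguities resolved in the fixtures, flagged by comments
  there: the discount rate (prose 5 %, parameter table 3 %/year — the
  table value is the default), the garbled China gemcitabine cycle cost
  (midpoint of its printed range, $153.15), the US laboratory-testing
  row whose printed range lies above its base (kept as a fixed, unsampled
  value), and the stable-utility range typo (0.0592 read as 0.592).
* Out of scope, as in the source analysis: indirect/societal costs,
  currency conversion, regional price variation, parametric
  survival-curve fitting, and EVPI/EVSI.
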