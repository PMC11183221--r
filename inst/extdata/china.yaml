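# China healthcare-perspective scenario: talazoparib vs physician's-choice
# chemotherapy for gBRCA1/2-mutated HER2-negative advanced breast cancer.
# All monetary values in 2022 USD.  Base values transcribe the published
# parameter tables; low/high are the printed sensitivity-analysis ranges.
country: china
currency: USD
settings:
  cycle_days: 21.0            # one chemotherapy cycle
  horizon_years: 5.0
  annual_discount_rate: 0.03  # parameter-table value (prose mentions 5%)
  half_cycle_correction: yes
  stable_to_death: 0.0        # no stable->death row in the base parameterization
  wtp_per_qaly: 38223.0       # 3 x 2022 per-capita GDP
  wtp_per_qaly_month: 3185.0  # published monthly framing (metadata, unused)
  gdp_per_capita: 12741.0
utilities:
  stable:    {family: beta, base: 0.74, low: 0.592, high: 0.888}  # printed low "0.0592" read as 0.592
  remission: {family: beta, base: 0.85, low: 0.680, high: 1.0}
  relapse:   {family: beta, base: 0.50, low: 0.400, high: 0.600}
  death:     {family: fixed, base: 0.0, low: 0.0, high: 0.0}
  # unused published alternates, retained for reference
  alternates:
    no_recurrence_after_chemotherapy: 0.94
    local_recurrence_first_year: 0.74
arms:
  intervention:
    name: talazoparib
    survival: {rr: 0.646, os_months: 24.3, pfs_months: 8.6, dor_months: 5.4}
    transition_sa:             # printed SA ranges for the primitive probabilities
      stable_to_remission:  {low: 0.1549, high: 0.2325}
      remission_to_relapse: {low: 0.0734, high: 0.1101}
      relapse_to_death:     {low: 0.0260, high: 0.0391}
    drug_cost:
      talazoparib: {family: triangular, base: 3440.97, low: 2752.78, high: 4129.16, weight: 1.0}
    ae_profile:
      anaemia:     {incidence: 0.66, cost: {family: gamma, base: 532.96, low: 479.66, high: 586.26}}
      neutropenia: {incidence: 0.36, cost: {family: gamma, base: 412.0, low: 370.8, high: 453.2}}
      fatigue:     {incidence: 0.34, cost: {family: gamma, base: 81.57, low: 73.41, high: 89.73}}
      back_pain:   {incidence: 0.22, cost: {family: gamma, base: 11.11, low: 9.99, high: 12.22}}
      nausea:      {incidence: 0.21, cost: {family: gamma, base: 64.0, low: 57.6, high: 70.4}}
  comparator:
    name: standard therapy
    survival: {rr: 0.111, os_months: 6.3, pfs_months: 5.6, dor_months: 3.1}
    transition_sa:
      stable_to_remission:  {low: 0.0290, high: 0.0436}
      remission_to_relapse: {low: 0.1235, high: 0.1853}
      relapse_to_death:     {low: 0.4193, high: 0.6289}
    # physician's-choice mixture; printed weights 44/40/10/7 sum to 101%
    # and are renormalized by the model.
    drug_cost:
      capecitabine: {family: triangular, base: 9.31, low: 7.45, high: 11.17, weight: 0.44}
      eribulin:     {family: triangular, base: 2481.76, low: 2413.04, high: 2895.64, weight: 0.40}
      # printed base garbled ("1017139.23-167.07"); midpoint of the printed
      # range adopted as base
      gemcitabine:  {family: triangular, base: 153.15, low: 139.23, high: 167.07, weight: 0.10}
      vinorelbine:  {family: triangular, base: 170.03, low: 136.02, high: 204.04, weight: 0.07}
    ae_profile:
      anaemia:     {incidence: 0.17, cost: {family: gamma, base: 532.96, low: 479.66, high: 586.26}}
      neutropenia: {incidence: 0.07, cost: {family: gamma, base: 412.0, low: 370.8, high: 453.2}}
      fatigue:     {incidence: 0.29, cost: {family: gamma, base: 81.57, low: 73.41, high: 89.73}}
      back_pain:   {incidence: 0.18, cost: {family: gamma, base: 11.11, low: 9.99, high: 12.22}}
      nausea:      {incidence: 0.12, cost: {family: gamma, base: 64.0, low: 57.6, high: 70.4}}
cost_table:
  laboratory_testing: {applies_to: all_alive, family: gamma, base: 75.47, low: 67.92, high: 83.02}
  ct_scan:            {applies_to: all_alive, family: gamma, base: 47.23, low: 42.51, high: 51.95}
  nursing_fee:        {applies_to: all_alive, family: gamma, base: 184.82, low: 166.33, high: 203.30}
  routine_follow_up:  {applies_to: all_alive, family: gamma, base: 7.05, low: 6.34, high: 7.75}
  docetaxel:          {applies_to: progressed_state, family: gamma, base: 884.92, low: 796.42, high: 973.41}
  prednisone:         {applies_to: progressed_state, family: gamma, base: 0.52, low: 0.30, high: 0.572}
  brca_profiling:     {applies_to: one_off, family: triangular, base: 1378.58, low: 1102.87, high: 1654.30}
# Published base-case totals for this comparison; inputs to the incremental
# worked example, not outputs of this pipeline.
reference_results:
  intervention: {cost: 12513.40, qaly: 3.06}
  comparator:   {cost: 8786.68, qaly: 1.56}
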