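# US healthcare-perspective scenario: talazoparib vs physician's-choice
# chemotherapy for gBRCA1/2-mutated HER2-negative advanced breast cancer.
# All monetary values in 2022 USD.  Base values transcribe the published
# parameter tables (which share the talazoparib and eribulin rows with the
# China table, as printed); low/high are the printed SA ranges.
country: us
currency: USD
settings:
  cycle_days: 21.0
  horizon_years: 5.0
  annual_discount_rate: 0.03
  half_cycle_correction: yes
  stable_to_death: 0.0
  wtp_per_qaly: 229200.0      # 3 x 2022 per-capita GDP
  wtp_per_qaly_month: 19100.0 # published monthly framing (metadata, unused)
  gdp_per_capita: 76400.0
utilities:
  stable:    {family: beta, base: 0.74, low: 0.592, high: 0.888}
  remission: {family: beta, base: 0.85, low: 0.680, high: 1.0}
  relapse:   {family: beta, base: 0.50, low: 0.400, high: 0.600}
  death:     {family: fixed, base: 0.0, low: 0.0, high: 0.0}
  alternates:
    no_recurrence_after_chemotherapy: 0.94
    local_recurrence_first_year: 0.74
arms:
  intervention:
    name: talazoparib
    survival: {rr: 0.646, os_months: 24.3, pfs_months: 8.6, dor_months: 5.4}
    transition_sa:
      stable_to_remission:  {low: 0.1549, high: 0.2325}
      remission_to_relapse: {low: 0.0734, high: 0.1101}
      relapse_to_death:     {low: 0.0260, high: 0.0391}
    drug_cost:
      talazoparib: {family: triangular, base: 3440.97, low: 2752.78, high: 4129.16, weight: 1.0}
    ae_profile:
      anaemia:     {incidence: 0.66, cost: {family: gamma, base: 1134.10, low: 1020.59, high: 1247.62}}
      neutropenia: {incidence: 0.36, cost: {family: gamma, base: 7818.0, low: 7036.2, high: 8599.8}}
      fatigue:     {incidence: 0.34, cost: {family: gamma, base: 9857.88, low: 9168.30, high: 10547.47}}
      back_pain:   {incidence: 0.22, cost: {family: gamma, base: 12534.53, low: 11280.55, high: 13787.46}}
      nausea:      {incidence: 0.21, cost: {family: gamma, base: 719.54, low: 465.65, high: 1027.80}}
  comparator:
    name: standard therapy
    survival: {rr: 0.111, os_months: 6.3, pfs_months: 5.6, dor_months: 3.1}
    transition_sa:
      stable_to_remission:  {low: 0.0290, high: 0.0436}
      remission_to_relapse: {low: 0.1235, high: 0.1853}
      relapse_to_death:     {low: 0.4193, high: 0.6289}
    drug_cost:
      capecitabine: {family: gamma, base: 6.38, low: 5.104, high: 7.656, weight: 0.44}
      eribulin:     {family: triangular, base: 2481.76, low: 2413.04, high: 2895.64, weight: 0.40}
      gemcitabine:  {family: gamma, base: 1195.48, low: 956.384, high: 1434.576, weight: 0.10}
      vinorelbine:  {family: gamma, base: 103.82, low: 83.056, high: 124.584, weight: 0.07}
    ae_profile:
      anaemia:     {incidence: 0.17, cost: {family: gamma, base: 1134.10, low: 1020.59, high: 1247.62}}
      neutropenia: {incidence: 0.07, cost: {family: gamma, base: 7818.0, low: 7036.2, high: 8599.8}}
      fatigue:     {incidence: 0.29, cost: {family: gamma, base: 9857.88, low: 9168.30, high: 10547.47}}
      back_pain:   {incidence: 0.18, cost: {family: gamma, base: 12534.53, low: 11280.55, high: 13787.46}}
      nausea:      {incidence: 0.12, cost: {family: gamma, base: 719.54, low: 465.65, high: 1027.80}}
cost_table:
  # printed base 12.675 with range 529.20-573.30 is internally inconsistent
  # (low > base); the printed base is kept and the range excluded from
  # sampling (family fixed).
  laboratory_testing: {applies_to: all_alive, family: fixed, base: 12.675, low: 529.20, high: 573.30}
  ct_scan:            {applies_to: all_alive, family: gamma, base: 828.0, low: 598.00, high: 1083.00}
  bone_imaging:       {applies_to: all_alive, family: gamma, base: 253.46, low: 202.76, high: 304.15}
  nursing_fee:        {applies_to: all_alive, family: gamma, base: 1617.0, low: 1316.0, high: 1917.0}
  routine_follow_up:  {applies_to: all_alive, family: gamma, base: 422.0, low: 348.10, high: 495.80}
  docetaxel:          {applies_to: progressed_state, family: gamma, base: 2228.95, low: 375.56, high: 2418.85}
  prednisone:         {applies_to: progressed_state, family: gamma, base: 23.4, low: 18.72, high: 28.08}
  brca_profiling:     {applies_to: one_off, family: triangular, base: 1380.17, low: 1104.136, high: 1656.204}
reference_results:
  intervention: {cost: 30987.66, qaly: 3.06}
  comparator:   {cost: 41211.09, qaly: 1.56}
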