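horizon_years: 85
discount_effects: 0.015
discount_costs: 0.04
productive_age_window: [25, 64]
wtp_max: 10000000
wtp_step: 10000
psa_draws: 1000
psa_trials: 100
seed: 1
strategies:
  no_ert:
    malignancy_excess_mortality: 0.10
  ert_base:
    malignancy_excess_mortality: 0.10
    ert_vial_unit_cost: 1985
    ert_cost_multiplier: 1.0
  ert_historical:
    malignancy_excess_mortality: 0.10
    ert_vial_unit_cost: 1985
    ert_cost_multiplier: 1.0
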