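# hypocost default parameter bundle -- Canada, 2015 CAN$,
# public health payer perspective.
#
# Incidence rates, severity split, resource-use probabilities and utilities
# are identical to the U.S. bundle (rates are assumed country-invariant).
# unit_costs, annual drug costs and utilities.disutility are SYNTHETIC
# plausible estimates -- see the note in us_2015.yaml; replace with your own
# payer prices for any substantive costing exercise.
schema: hypocost-params/1
country: Canada
currency: 2015 CAN$
cohorts:
  "65-79":
    diabetes_duration: 15.6
    hba1c: 7.1
    bmi: 31.1
    gfr: 61.0
  "80plus":
    diabetes_duration: 17.8
    hba1c: 7.0
    bmi: 28.2
    gfr: 45.0
strategies:
  metformin:
    base_rate: 1.0
    daily_smbg_tests: 0.94
    daily_injections: 0
    annual_drug_cost: 65
  sulfonylurea:
    base_rate: 3.0
    daily_smbg_tests: 1.16
    daily_injections: 0
    annual_drug_cost: 75
  dpp4:
    base_rate: 1.0
    daily_smbg_tests: 0.94
    daily_injections: 0
    annual_drug_cost: 990
  tzd:
    base_rate: 1.0
    daily_smbg_tests: 0.94
    daily_injections: 0
    annual_drug_cost: 270
  glp1:
    base_rate: 1.3
    daily_smbg_tests: 0.94
    daily_injections: 1
    annual_drug_cost: 2400
  basal_insulin:
    base_rate: 6.3
    daily_smbg_tests: 2.08
    daily_injections: 1
    annual_drug_cost: 1560
severity:
  p_mild: 0.95
  p_moderate: 0.04
  p_severe: 0.01
resource_use:
  p_hcp_contact: 0.14
  p_assay_per_contact: 1.0
  n_extra_smbg: 3.9
  p_glucagon_moderate: 0.02
  severe_branches:
    gp: 0.26
    np: 0.13
    outpatient: 0.20
    er_only: 0.17
    hospitalization: 0.24
  p_glucagon_severe: 0.25
  p_ambulance: 1.00
  p_death_given_hospitalization: 0.20
risk_constants:
  duration_base: 1.037
  duration_cap: 20.0
  duration_offset: 9.0
  a1c_base: 0.82
  a1c_ref: 7.0
  bmi_base: 0.95
  bmi_floor: 21.0
  bmi_cap: 35.0
  bmi_ref: 33.0
  gfr_scale: 22700
  gfr_exponent: -0.86655
  gfr_floor: 15.0
  gfr_ref: 60.0
  gfr_variant: adopted
unit_costs:                   # SYNTHETIC 2015 Canadian public-payer estimates, CAN$
  gp_visit: 77.00
  np_visit: 62.00
  outpatient_visit: 160.00
  er_visit: 304.00
  hospitalization: 7120.00
  ambulance: 240.00
  glucagon_kit: 120.00
  blood_glucose_assay: 10.00
  smbg_strip: 0.73
  smbg_lancet: 0.18
  needle: 0.19
  home_monitor_annual: 20.00
utilities:
  u_base: 0.844
  disutility:
    mild_daytime: 0.0041
    mild_nocturnal: 0.0067
    modsev_daytime: 0.0592
    modsev_nocturnal: 0.0616
  p_daytime_mild: 0.75
  p_daytime_modsev: 0.60
  fatal_year_fraction_lost: 0.5
settings:
  wtp_threshold: 53891        # 2014 Canadian per-capita GDP, CAN$/QALY
  exchange_rate_us_to_can: 1.0720
  time_horizon: 1
  discount_rate: 0
population:
  n_tight_control_users: 128626
  rx_ratio_su_to_insulin: 2.3
  share_80plus: 0.26
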