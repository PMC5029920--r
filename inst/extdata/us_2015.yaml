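# hypocost default parameter bundle -- United States, 2015 US$,
# Medicare payer perspective.
#
# Provenance notes:
#   * cohorts, strategies (base rates, SMBG frequencies), severity split,
#     resource-use probabilities, base utility, daytime proportions and
#     economic settings carry published base-case values.
#   * unit_costs and utilities.disutility are SYNTHETIC: plausible 2015
#     Medicare / published-valuation estimates constructed for the packaged
#     defaults because the original supplementary cost tables are not
#     redistributable here.  Replace with your own payer prices for any
#     substantive costing exercise -- every downstream cost output is
#     conditional on this section.
schema: hypocost-params/1
country: US
currency: 2015 US$
cohorts:
  "65-79":
    diabetes_duration: 15.6   # years
    hba1c: 7.1                # %
    bmi: 31.1                 # kg/m^2
    gfr: 61.0                 # ml/min
  "80plus":
    diabetes_duration: 17.8
    hba1c: 7.0
    bmi: 28.2
    gfr: 45.0
strategies:
  metformin:
    base_rate: 1.0            # mild events / person-year at reference profile
    daily_smbg_tests: 0.94
    daily_injections: 0
    annual_drug_cost: 132     # incl. dispensing fees (synthetic)
  sulfonylurea:
    base_rate: 3.0
    daily_smbg_tests: 1.16
    daily_injections: 0
    annual_drug_cost: 156
  dpp4:
    base_rate: 1.0
    daily_smbg_tests: 0.94
    daily_injections: 0
    annual_drug_cost: 2010
  tzd:
    base_rate: 1.0
    daily_smbg_tests: 0.94
    daily_injections: 0
    annual_drug_cost: 696
  glp1:
    base_rate: 1.3
    daily_smbg_tests: 0.94
    daily_injections: 1
    annual_drug_cost: 1980
  basal_insulin:
    base_rate: 6.3
    daily_smbg_tests: 2.08
    daily_injections: 1
    annual_drug_cost: 1068
severity:
  p_mild: 0.95
  p_moderate: 0.04
  p_severe: 0.01
resource_use:
  p_hcp_contact: 0.14         # primary-care contact after any event
  p_assay_per_contact: 1.0    # quantitative glucose assay per contact
  n_extra_smbg: 3.9           # additional SMBG tests after any event
  p_glucagon_moderate: 0.02
  severe_branches:
    gp: 0.26
    np: 0.13
    outpatient: 0.20
    er_only: 0.17
    hospitalization: 0.24
  p_glucagon_severe: 0.25     # on transported (ER / hospitalization) pathways
  p_ambulance: 1.00           # on transported pathways
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
  gfr_variant: adopted        # "adopted" or "printed_div" (divides by 1.2)
unit_costs:                   # SYNTHETIC 2015 Medicare estimates, US$
  gp_visit: 73.00
  np_visit: 62.00
  outpatient_visit: 150.00
  er_visit: 622.00
  hospitalization: 10925.00
  ambulance: 429.00
  glucagon_kit: 180.00
  blood_glucose_assay: 5.50
  smbg_strip: 0.33
  smbg_lancet: 0.10
  needle: 0.15
  home_monitor_annual: 18.00
utilities:
  u_base: 0.844               # uncomplicated type 2 diabetes, utility/year
  disutility:                 # QALY decrement per event (synthetic defaults
    mild_daytime: 0.0041      # from published time-trade-off valuations)
    mild_nocturnal: 0.0067
    modsev_daytime: 0.0592
    modsev_nocturnal: 0.0616
  p_daytime_mild: 0.75
  p_daytime_modsev: 0.60
  fatal_year_fraction_lost: 0.5
settings:
  wtp_threshold: 54630        # 2014 US per-capita GDP, US$/QALY
  exchange_rate_us_to_can: 1.0720
  time_horizon: 1
  discount_rate: 0
population:
  n_tight_control_users: 1200000  # insulin/sulfonylurea users in very tight control
  rx_ratio_su_to_insulin: 2.3     # 41% / 18%
  share_80plus: 0.26
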