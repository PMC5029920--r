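# hypocost

Drug-induced hypoglycemia is a common, costly and often under-weighted
harm of glucose-lowering therapy in older adults with type 2 diabetes.
`hypocost` implements a one-year decision-tree cost-effectiveness model
that compares six medication classes — metformin, sulfonylureas, DPP-4
inhibitors, thiazolidinediones, GLP-1 receptor agonists and basal insulin
(glargine) — in adults aged 65–79 and 80+, from the U.S. Medicare and
Canadian public-payer perspectives. It is written for health-economics
and outcomes researchers who want the whole pipeline — incidence, costing,
QALYs, ICERs, deterministic and probabilistic sensitivity analysis,
budget impact — as tested, configurable, pipe-friendly R functions rather
than a spreadsheet.

## The model in brief

Annual **mild hypoglycemia incidence** per person is a medication-class
base rate times four multiplicative risk factors evaluated at the
cohort's average profile (diabetes duration *d*, HbA1c, BMI, GFR):

```
rate_mild = base_rate
          × 1.037^(min(d, 20) − 9)
          × 0.82^(A1c − 7.0)
          × 0.95^(clamp(BMI, 21, 35) − 33)
          × 22700^(clamp(GFR, 15, 60)^−0.86655 − 60^−0.86655)
```

Moderate and severe events are added so all events split 95/4/1 by
severity. A decision tree then prices each event (primary-care follow-up,
self-monitoring, glucagon, and for severe events a management branch
among GP / nurse practitioner / outpatient / ER / hospitalization with
ambulance on the transported pathways), adds annual therapy cost, applies
a 20% fatality rate to hospitalized events
(`p_fatal = 1 − exp(−rate_severe × 0.24 × 0.20)`), and accrues QALYs as
the base utility 0.844 minus daytime/nocturnal-weighted per-event
disutilities and the fatality loss. Strategies are compared pairwise by
incremental cost per QALY gained (`ICER = ΔC/ΔE`) with dominance
classification, against per-capita-GDP willingness-to-pay thresholds
(US\$54,630; CAN\$53,891). A patient-level microsimulation realizes the
same tree stochastically and serves as a Monte-Carlo oracle for every
closed-form expectation.

All inputs live in YAML bundles (`inst/extdata/us_2015.yaml`,
`canada_2015.yaml`). Unit costs and per-event disutilities are
*synthetic plausible defaults* (the original supplementary price tables
are not redistributable) and are meant to be replaced with your payer's
prices; incidence inputs, probabilities and utilities carry the published
base-case values. See `vignette("hypocost-methods")` for every modelling
convention and its rationale.

## Worked example

```r
library(hypocost)

us <- default_parameters("US")

event_rates(us)[, c("strategy", "cohort", "mild_2dp", "moderate_severe_2dp")]
#>    strategy      cohort mild_2dp moderate_severe_2dp
#>  1 metformin     65-79      1.37                0.07
#>  2 metformin     80plus     1.91                0.10
#>  3 sulfonylurea  65-79      4.12                0.22
#>  4 sulfonylurea  80plus     5.73                0.30
#>  ...
#> 11 basal_insulin 65-79      8.65                0.46
#> 12 basal_insulin 80plus    12.04                0.63
```

Metformin users experience 1.37 mild events/person-year at ages 65–79 and
1.91 at 80+ (renal decline and longer duration raise risk); sulfonylureas
triple that, insulin multiplies it by 6.3. Costs and QALYs follow:

```r
out <- evaluate_strategies(us)
dplyr::select(out, strategy, cohort, annual_total_cost, qaly)
#>    strategy      cohort annual_total_cost  qaly
#>  1 metformin     65-79                359 0.833
#>  3 sulfonylurea  65-79                541 0.811
#>  7 tzd           65-79                923 0.833
#> 11 basal_insulin 65-79               1855 0.774
#>  ... (dollar values conditional on the bundle's unit-cost configuration)

compare_strategies(out, "sulfonylurea", wtp = us$settings$wtp_threshold)
#>    cohort strategy      status    icer   cost_effective
#>  1 65-79  metformin     dominant      NA TRUE
#>  2 65-79  tzd           icer       17118 TRUE
#>  3 65-79  dpp4          icer       75958 FALSE
#>  4 65-79  glp1          icer       91639 FALSE
#>  5 65-79  basal_insulin dominated     NA FALSE
```

Metformin dominates every alternative (cheaper *and* more effective);
basal insulin is dominated by sulfonylureas; thiazolidinediones and, in
the 80+ cohort, DPP-4 inhibitors buy QALYs below the willingness-to-pay
threshold. Uncertainty and budget impact:

```r
psa <- run_psa(us, "65-79", psa_spec(1000, seed = 1))
autoplot(ceac(psa))        # acceptability curves; injectables sit at 0%

tornado(us, "dpp4", "sulfonylurea", "65-79") |> autoplot()

population_costs(default_parameters("Canada"))
#> 128,626 Canadian insulin/sulfonylurea users in very tight control
#> (38,978 / 89,648) incur CAN$28.8M/year of hypoglycemia-attributable cost
#> under the packaged synthetic prices

disinvestment_savings(us, disinvestment_scenario("single_replacement", "metformin"))
#> replacing all 1.2M U.S. tight-control insulin/sulfonylurea users with
#> metformin saves ~US$719M/year under the packaged synthetic prices
```

`tidy()`/`glance()` methods are provided for PSA and tornado objects, and
a thin CLI (`inst/cli/hypocost.R`) exposes `rates`, `cea`, `dsa`, `psa`
and `population` subcommands for shell pipelines.

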