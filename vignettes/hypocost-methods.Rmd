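---
title: "Methods: a one-year decision-tree model of drug-induced hypoglycemia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a one-year decision-tree model of drug-induced hypoglycemia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypocost)
```

## The model

`hypocost` evaluates the short-term (one-year, undiscounted) economic
consequences of drug-induced hypoglycemia in older adults with type 2
diabetes, for six glucose-lowering medication classes — metformin,
sulfonylureas, DPP-4 inhibitors, thiazolidinediones, GLP-1 receptor
agonists and basal insulin (glargine) — in two age cohorts (65–79 years,
80 years and older) and from two payer perspectives (U.S. Medicare, 2015
US\$; Canadian public payer, 2015 CAN\$). The six classes are assumed
approximately equivalent in glycemic efficacy, so the comparison isolates
hypoglycemia-related harms and costs; clinical-effectiveness differences
and non-hypoglycemia harms are out of scope by design.

The structure is a decision tree evaluated in closed form. The decision
node is the choice of medication class; chance nodes realize, for each
person-year: the number of hypoglycemic events, their severity (mild —
self-treated; moderate — non-medical third-party help; severe — medical
assistance), the management branch of each severe event (GP, nurse
practitioner, outpatient practice, emergency room only, hospitalization),
per-event resource use, and survival of hospitalized events. Because every
output is an expectation and event streams enter linearly, the analytic
module never simulates: it multiplies rates by per-event expected costs
and disutilities.

## Incidence: the risk equation

The annual rate of *mild* hypoglycemia is a medication-class base rate
(metformin/DPP-4/TZD 1.0, GLP-1 1.3, sulfonylureas 3.0, basal insulin 6.3
events/person-year) multiplied by four dimensionless risk factors
evaluated at the cohort's average clinical profile:

* duration: $1.037^{\min(d,\,20) - 9}$ (years of diabetes),
* glycemic control: $0.82^{\mathrm{A1c} - 7.0}$,
* body mass: $0.95^{\mathrm{clamp}(\mathrm{BMI},\,21,\,35) - 33}$,
* renal function: $22700^{\,\mathrm{clamp}(\mathrm{GFR},\,15,\,60)^{-0.86655} - 60^{-0.86655}}$.

Each factor is 1 at its reference value and flat outside its clamp
interval. The source expression for the renal factor is typographically
corrupted; the reading above is adopted because it is the only one that
(a) yields a unit multiplier for the 65–79 profile (GFR 61), reproducing
the published metformin rate 1.37, and (b) reproduces the published 80+
rates (1.91, 5.73). The variant that divides the multiplier by 1.2 is
implemented behind `risk_constants$gfr_variant = "printed_div"` for audit,
but it cannot reproduce those rates and is not the default.

**Severity convention.** The equation output is interpreted as the mild
rate. Moderate and severe events are added on top so that the severity
distribution of all events is 95/4/1; equivalently the combined
moderate/severe rate is $\text{mild} \times 0.05/0.95$. The combined 5%
class is used for incidence, but moderate (4%) and severe (1%) remain
distinct for costing because they consume different resources. The
published table is internally inconsistent here: its
metformin/DPP-4/TZD/sulfonylurea-80+ cells follow this convention, while
its basal-insulin and GLP-1 cells are closer to treating the equation
output as the *total* rate. No single convention reproduces every printed
cell; the package follows the mild-rate convention throughout and its test
suite quarantines the irreproducible cells explicitly rather than
tolerating drift. Published headline totals (e.g. 2.01 and 6.03
events/person-year for metformin and sulfonylureas in the 80+ cohort) are
sums of the two *independently rounded* components, and
`event_rates()` exposes `*_2dp` columns computed exactly that way, with
half-up rounding.

## Costs

Per-event expected costs follow the tree:

* every event (any severity): primary-care contact with probability 0.14,
  one glucose assay per contact, and 3.9 additional self-monitoring tests
  (strip + lancet);
* moderate events: a glucagon injection with probability 0.02;
* severe events: one management branch with probabilities
  0.26/0.13/0.20/0.17/0.24; the transported pathways (ER-only and
  hospitalization, jointly 41%) additionally incur ambulance use
  (probability 1.00) and glucagon (0.25). The source does not state which
  branches the ambulance and glucagon attach to; they are charged on the
  transported pathways because those probabilities were measured in
  EMS-attended and ED cohorts. Alternative ambulance figures quoted in the
  source (85% of ED presentations, 35% of calls transported) are available
  as configuration overrides, not defaults.

Annual therapy cost adds drug acquisition (including dispensing fees),
365 × daily SMBG tests × (strip + lancet) — 0.94/day for oral
non-secretagogues and GLP-1, 1.16 for sulfonylureas, 2.08 for insulin —
needles (one per injection; GLP-1 defaults to one injection/day,
liraglutide-style; twice-daily exenatide dosing is a config override), and
an annualized home monitor.

**Unit costs are configuration, not code.** The packaged YAML bundles
carry *synthetic* plausible 2015 price sets (clearly flagged in the
files); the original supplementary price tables are not redistributable
here. Consequently the packaged defaults reproduce the published
qualitative structure — orderings, dominance patterns, acceptability — and
the right cost magnitudes, but not the printed dollar columns, which are
conditional on the original prices. The test suite asserts exactly this
split: rates and structural results exactly, dollar columns only through
linearity and configuration-swap properties, and the published
cost-effectiveness table through the published per-person costs and QALYs
taken as direct inputs (`reference_outcomes()`).

## Utilities and fatality

QALYs accrue over one year as the base utility for uncomplicated diabetes
(0.844) minus per-event disutilities and a fatality loss. Disutilities are
stratified by severity class (mild vs moderate/severe) and timing, with
75% of mild and 60% of moderate/severe events occurring in daytime. The
packaged per-event decrements (daytime/nocturnal mild 0.0041/0.0067;
moderate/severe 0.0592/0.0616) come from the published time-trade-off
valuation study of hypoglycemic health states in a North American type 2
diabetes population; they are configuration like the unit costs.

Only hospitalized severe events carry mortality (0.20 one-year fatality).
Treating fatal hospitalizations as thinned Poisson events gives
$p_{\text{fatal}} = 1 - e^{-\lambda_{\text{severe}} \times 0.24 \times 0.20}$.
The source does not state how death enters the QALY total within the
one-year horizon; the package charges half a year of base utility per
fatal event year (`fatal_year_fraction_lost = 0.5`, configurable), and
fatal events do not truncate the cost/disutility streams — the simplest
convention consistent with an annual expectation model. Expected QALYs are
floored at zero.

## Cost-effectiveness

`icer()` classifies each pairwise comparison: *dominant* (no dearer, no
less effective, at least one strict), *dominated* (the reverse),
*equivalent* (both deltas at machine precision), otherwise an ICER
$\Delta C / \Delta E$. Cheaper-but-less-effective (southwest) ratios are
flagged rather than ranked, and zero-QALY-difference comparisons resolve
by the cost sign. `compare_strategies()` orders output by decreasing
cost-effectiveness. No extended-dominance frontier is constructed by
default — the published comparison is pairwise against a single reference
(metformin, and sulfonylureas as a second reference) — though the ordering
makes frontier reasoning easy downstream. Willingness-to-pay thresholds
are the 2014 per-capita GDPs: US\$54,630 and CAN\$53,891 (US\$50,271 ×
1.0720).

## Sensitivity analysis

**One-way (tornado).** Each scalar parameter in the uncertain sections
(strategies, severity, resource use, unit costs, utilities) is moved to
±25% of base (probabilities capped at 1) with everything else at base, and
the pairwise ICER is recomputed. Probabilities that are components of a
categorical distribution (severity split, severe-event branches) are
perturbed with their siblings renormalized proportionally, so every
scenario remains a valid distribution. Dominance at an endpoint is encoded
as a signed infinity for sorting and labelled in text. The source does not
list which parameters entered its tornado figures, so the default sweep
covers every scalar.

**Probabilistic.** The source prescribes gamma distributions for incidence
rates, costs and disutilities, a beta for the base utility, ±25% ranges
and 1,000 iterations, but not how ±25% maps to distribution parameters.
The package interprets ±25% as a 95% interval half-width, giving every
sampled parameter standard deviation $0.25 \times \text{mean}/1.96$, with
gamma/beta shapes moment-matched to that mean and SD — the common
convention in health-technology assessment. Parameters are sampled jointly
but independently (no correlation structure is specified by the source).
Incidence uncertainty enters through the six medication base rates; the
cohort covariates are fixed population averages. `range_fraction = 0`
collapses every distribution to its mean, which the tests use to verify
the PSA evaluator agrees exactly with the base-case evaluator.

**CEAC.** A strategy is "cost-effective" at a given willingness-to-pay if
it maximizes net monetary benefit ($E \times \lambda - C$) among all six
strategies in that iteration; ties (probability zero under continuous
draws) go to the cheaper strategy, and probabilities sum to one at every
grid point by construction.

## Population budget impact

National figures scale per-person outcomes by user counts: 1.2 million
U.S. (128,626 Canadian) older adults in very tight control using insulin
or sulfonylureas, split by the 2.3 sulfonylurea-to-insulin prescription
ratio — giving 38,978 insulin and 89,648 sulfonylurea users in Canada —
and by the 26% share aged 80+. Counts are rounded to the nearest person
with remainders balanced so partitions sum exactly; all outputs are linear
in counts up to that rounding. The headline "cost of drug-induced
hypoglycemia" uses the hypoglycemia-attributable component only;
disinvestment savings (no replacement; 100% replacement with the most
cost-effective agent; a 50/50 mix of the two most cost-effective agents)
use total cost, since switching drugs changes both therapy and
hypoglycemia spending. The source prints a U.S. combined figure whose last
three digits disagree with the sum of its own components (…473 vs …743, a
transposition); the package always reports the computed sum.

## The microsimulation oracle

`simulate_patients()` realizes the tree patient by patient: severity-class
event counts are independent Poisson draws (equivalent to a Poisson total
thinned 95/4/1), severe-event branches are categorical via successive
binomial splits, resource use is binomial per event, a hospitalized event
is fatal with probability 0.20, and death ends QALY accrual at a uniform
time in the remaining year (expected loss = half a year, matching the
analytic convention; costs and disutilities are not truncated, also
matching). Every analytic expectation is therefore the exact population
mean of the generator, which yields the package's strongest test: at
n = 200,000 patients per cell, empirical mean hypoglycemia cost and QALYs
must sit within three standard errors of the closed-form values for all
24 strategy × cohort × country cells, and severity proportions must
converge to 95/4/1. That n makes the Monte-Carlo standard error a
fraction of a percent of each mean while keeping the full 24-cell check
inside a few seconds.

What the generator deliberately does **not** emulate: patient-level
heterogeneity beyond the two cohort profiles, within-year dependence
between events (no seasonality, no event clustering, no
post-hospitalization rate change), behavioral responses to events, and
multi-drug regimens. Passing the oracle test shows the analytic
expectations and the stochastic realization of the *stated* model agree —
it does not validate the model against real claims data.

## Numerical choices and edge cases

* Half-up rounding (`round_half_up()`) for published-table mirroring; full
  precision everywhere internally.
* Validation is total and errors name the failing field; severity and
  branch probabilities must sum to 1 within 1e-8; bundles reject unknown
  keys with a warning.
* Machine-precision ties in `icer()` are "equivalent", never dominance.
* Gamma sampling of a zero-valued parameter is impossible; such
  parameters are held fixed with a warning.
* A time horizon other than 1 year or a nonzero discount rate is rejected:
  the model is annual by construction.

## Problem sizes used in the packaged checks

The test suite and acceptance script run the full base case (12 cells per
country), 1,000-iteration PSAs for all four country × cohort cells, and
the 24-cell microsimulation oracle at 200,000 patients per cell — the
same iteration count the source prescribes for its Monte-Carlo analysis,
and an oracle size chosen so sampling error is negligible relative to the
tested tolerances.
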