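---
title: "Methods: a Markov cost-utility model of enzyme replacement therapy in type 1 Gaucher disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cost-utility model of enzyme replacement therapy in type 1 Gaucher disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gauchercea)
```

## The decision problem

Type 1 Gaucher disease (GD I) is a rare lysosomal storage disorder in
which glucocerebroside accumulates in macrophages, producing
organomegaly, cytopenia and progressive, largely irreversible end-organ
damage: splenectomy, bone complications, and an elevated risk of
associated malignancies. Enzyme replacement therapy (ERT) reverses most
visceral and haematological manifestations but is among the most
expensive chronic treatments in medicine, so its value is naturally
framed as a cost-effectiveness question: what does a lifetime of ERT buy,
in years free of end-organ damage (YFEOD) and in quality-adjusted life
years (QALYs), compared with standard medical care, and at what cost per
unit gained?

`gauchercea` implements a complete, testable pipeline for that question:
a parameter data model, registry-based calibration of every model input,
a discrete-time cohort engine with a microsimulation twin, an economics
layer (differential discounting, ICERs, scenarios), probabilistic
sensitivity analysis (PSA), and a synthetic-registry generator that makes
the whole chain verifiable against known ground truth.

## Model structure

The disease course is modelled with eight mutually exclusive states:
*asymptomatic*, *signs/symptoms*, *recovery*, *splenectomy*, *bone
complication*, *multiple complications*, *malignancy* and *dead*
(`gd_states()`). Recovery is reachable only from signs/symptoms and only
under ERT, because splenectomy and bone damage are irreversible; the
YFEOD outcome counts time in the asymptomatic, signs/symptoms and
recovery states. Cycles are one year; a closed cohort enters at birth and
is followed for 85 cycles or until death.

Within a cycle, survival is evaluated first: every alive state carries
the age-specific background death probability from a period life table,
and the malignancy state adds a constant excess death probability
(additive on the annual scale, capped at 1), since these malignancies
(multiple myeloma, hepatocellular carcinoma) carry substantial mortality
of their own. Conditional on surviving the cycle, the annual disease
transition probabilities apply. This event ordering is a modelling
convention — the alternative (transitions first) is a one-line change in
`transition_matrix()` — and is pinned down by unit tests. No half-cycle
correction is applied: rewards accrue at cycle start, matching the
description of the original model, which mentions none.

In ERT arms the asymptomatic state uses natural-history exit
probabilities and carries no medication cost, reflecting the base-case
policy that therapy starts only when signs/symptoms appear.

## Calibration from registry data

All model inputs are estimable from patient-level registry records.

**Transition probabilities.** For each ordered state pair, the time from
state entry to the transition is analysed with the Aalen–Johansen
cumulative incidence estimator (`cumulative_incidence_competing()`,
computed through `survival::survfit` on the multi-state endpoint), which
is the standard competing-risk correction of Kaplan–Meier; a naive
1 − KM variant is available for sensitivity. The curve is then read with
the median rule: if cumulative incidence reaches 50%, the pair
(0.5, first crossing time) is taken; otherwise the curve value and time
at the last step with at least four patients still at risk. The
cumulative proportion `P` over `t` years is converted to a constant
annual probability with the Markov correction
`p = 1 − (1 − P)^(1/t)` (`annualize_transition()`), whose `t`-fold
compounding reproduces `P` exactly; the naive ratio `P/t` is computed
only as a diagnostic (`annualize_linear()`). Beta shape parameters for
the PSA are formed from the point estimate and the number of patients at
risk.

This estimator is faithful to the published procedure but not unbiased:
when a destination's cumulative incidence plateaus well below 50%
because of strong competing exits, reading the plateau at a late time
and annualizing understates the cause-specific annual probability. In a
controlled experiment (single entry cohort, total annual exit 0.20,
destination share 0.18) the asymptotic error is about −0.008 on the
annual probability scale. Users should treat calibrated values for
heavily-competed transitions as mildly conservative.

**Utilities.** Quarterly EQ-5D utilities (consumed as already-scored
numbers; the UK time-trade-off tariff and its Dutch replication are out
of scope) are averaged in two stages — per patient within a state, then
over patients — so that heavily observed patients do not dominate
(`mean_state_utility()`). Confidence intervals are bias-corrected and
accelerated (BCa) bootstrap over *patients* (`boot::boot.ci`); a
single-patient state returns its mean with the interval flagged
unavailable. Death has utility 0 by convention; tariff values may reach
−0.594.

**Costs** (2009 euros throughout, no indexation). ERT medication costs
follow the three-step rule: episode-length-weighted vials of 400 IU per
month per patient, averaged over patients, times 12 and the vial unit
cost (default €1,985). Hospital costs are product-sums of procedures and
unit costs, annualized per patient by follow-up time in the state.
Out-of-hospital costs are quarterly volumes times unit costs, times 4.
Production loss follows the human-capital method: sick-leave days per
fortnight × 26 × mean hours per workday for employed patients, a full
working year for patients with GD-attributable work disability, zero for
patients out of work for unrelated reasons, all valued at €30/hour. The
friction-cost method is deliberately not implemented.

## Economics

Effects are discounted at 1.5%/year and costs at 4%/year (the Dutch
guideline pair used in the analysis), with rewards at cycle start and
the first cycle undiscounted; rate 0 recovers undiscounted totals
exactly. The ICER is the cost difference over the effect difference,
reported per YFEOD and per QALY, with dominance flags when the signs
disagree. Four scenarios modify the base case: adding production-loss
costs within the productive window (ages 25–64); multiplying ERT
medication costs by 0.75; and two historical variants that start the
cohort from a prevalent 1991-style distribution over disease states and
use the historical ERT transition set. The historical scenarios keep the
life table indexed from age 0 — a simplification, since the prevalent
cohort is in reality age-heterogeneous.

## Probabilistic sensitivity analysis

Second-order uncertainty draws every transition probability from its
beta distribution; in `all_parameters` mode, utilities, cost components
and vial rates are additionally drawn from triangular distributions with
the point estimate as mode and the 95% limits as support, and the same
sampled utility/cost tables apply to both arms within a draw (treated
and untreated patients share utilities and non-ERT costs within a
state). Each draw is evaluated either deterministically (cohort mode) or
as the mean of first-order microsimulation trials (default 100 patients
per arm) with common random numbers across arms to reduce the variance
of the increments. Outputs are the cost-effectiveness plane, quadrant
shares (boundary values count to the positive side), the acceptability
curve as the net-monetary-benefit exceedance probability over a
willingness-to-pay grid (default €0–10,000,000 per QALY in €10,000
steps), and interpolated willingness-to-pay readouts at given
probabilities.

Beta shapes are fitted from printed means and 95% limits by constraining
the mean exactly (`alpha/(alpha+beta) = mean`) and choosing the
remaining free parameter to reproduce the central 95% interval,
numerically; if the limits cannot be matched to within 5e-3 the fit
falls back to method of moments on the implied standard deviation
`(ucl − lcl)/3.92` and flags itself (`fit_beta_from_ci()`). If sampled
outgoing probabilities from a state sum beyond 1 they are rescaled
proportionally, preserving relative risks.

## The synthetic registry

`simulate_registry()` generates the six record sets the calibration
consumes — episodes, quarterly EQ-5D observations (both tariffs), dose
episodes, procedure logs, quarterly out-of-hospital visit counts, and
work records — from a known `strategy_spec` truth. Patients enter at a
random integer age (10–50) in a prevalent mix of disease states,
emulating a national cohort enrolled when a therapy reaches the market,
and are followed for 20 years (a 1991–2011-style window) under annual
competing transitions plus life-table mortality. Episode cycles are
measured from state entry for every entrant, and each event is placed
uniformly within its cycle year, so all entrants into a state face the
same real-valued sojourn-time law. Ten percent of patients are censored
uniformly before the administrative end.

Observation noise is truncated-normal on the utility scale (SD 0.05,
clipped to the tariff range; at this SD the clipping bias is below
0.002). Dose rates vary log-normally across patients (CV 0.3) with
episode-level switching to exercise the episode-weighting logic.
Procedure and visit counts are Poisson with rates implied by the truth
cost tables; work profiles split each state's production-loss truth
half-and-half between sick leave among the employed (60% employment) and
permanent disability, so `truth_report()` can echo the generating cost
tables unchanged.

What the generator does *not* emulate: confounding by indication,
treatment interruptions (e.g. supply shortages), recording quality
differences between retrospective and prospective data, and age- or
severity-dependent transition probabilities. Passing recovery tests
therefore demonstrates the statistical machinery is correct, not that
real registry estimates are unbiased.

## The packaged fixture and its limits

The fixture under `inst/extdata/basecase/` transcribes the published
per-state utilities (UK and NL tariffs), annual cost components and ERT
vial rates with their 95% limits. The transition tables and the life
table, however, are **synthetic placeholders** (marked
`synthetic_placeholder`, file `lifetable_synthetic.csv`): the study's
transition probabilities live in supplementary tables that are not
redistributed here, and the national life table is external data. The
placeholder values were chosen once as plausible for a slowly
progressive disorder (natural-history exits of 0.3–5% per year, ERT
recovery at 18% per year with roughly halved complication rates) and are
*not* tuned to reproduce the published results; model outputs from the
packaged fixture are therefore illustrative. The acceptance checks that
compare them against the published tables document the gap and will pass
only once a user transcribes the true inputs into the same CSV schema.
The malignancy excess mortality (stated only qualitatively in the source)
ships as a required fixture field, placeholder 0.10/year — the order of
survival observed in multiple myeloma and hepatocellular carcinoma.
The two historical starting distributions, likewise not printed, are
config-driven placeholder rows in `start_distribution.csv`.

## Numerical choices and problem sizes

Tolerances: occupancy conservation to 1e-10 over 85 cycles; the
annualization inverse to 1e-12; beta-fit mean to 1e-6 and limits to
5e-3; ICER identity to 1e-9. Ties in episode analysis follow
`survival`'s convention (events before censorings at equal times). The
test suite exercises the engine against explicit matrix-power
enumeration on randomly generated small chains, recovers generating
parameters from a 10,000-patient synthetic registry (the package's
standard large-registry size, about 90 s of compute), and runs the PSA
at its full 1,000 × 100 design (about a minute with microsimulation);
quick checks use 100 draws × 20 trials.

## Known limitations

* The calibration estimator inherits the published median-rule bias
  under strong competing risks (quantified above).
* Historical scenarios age the prevalent cohort from age 0.
* Transition probabilities are age-invariant within an arm; only
  mortality is age-specific.
* No EVPI, budget impact, friction costing, or substrate reduction
  therapy comparator.
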