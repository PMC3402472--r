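---
title: "Methods: generalized cost-effectiveness analysis of CVD primary prevention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generalized cost-effectiveness analysis of CVD primary prevention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdcea)
```

## The model in one page

The package asks which mix of interventions — population-wide salt
limits, a community heart health program, six drug classes offered by
absolute risk band, and three behaviour-change strategies — buys the most
cardiovascular health per dollar, over the lifetime of everyone aged
35–84 who has never had an ischaemic heart disease (IHD) or stroke event.

Four stages:

1. A **synthetic world**: an individual-level risk-factor survey, age/sex
   tables of first-event incidence, case fatality, background mortality
   and secular trends, health-state weights, and disease treatment costs.
2. A **risk engine** that predicts five-year first-event risk per
   individual, rescales predictions to match observed event rates, and
   stratifies the eligible population into treatment-eligibility bands
   (≥15%, 10–14%, 5–9%, <5% five-year risk).
3. A **four-state Markov cohort model** (well → IHD / stroke / dead) run
   until extinction for each age × sex × risk-band cohort, yielding
   discounted life years, health-adjusted life years (DALY or QALY
   framework) and cost streams.
4. A **generalized CEA layer**: every strategy, including current
   practice, is compared against a back-calculated "do nothing"
   counterfactual; a greedy expansion pathway traces the efficiency
   frontier; Monte Carlo parameter draws give 95% uncertainty intervals
   and the acceptability frontier.

## The synthetic world, and what a green test does not establish

No public accessions exist for the individual-level survey and the
derived national event rates the original analysis style relies on, so
every input here is generated. Defaults are order-of-magnitude plausible
for a Western population in 2008 — IHD incidence rising exponentially
from ≈1/1000 to ≈30/1000 person-years between ages 35 and 84, case
fatality 0.2–0.4 rising with age, smoking prevalence in the twenties of
percent, systolic blood pressure near 125–130 mmHg with SD 15 — but they
are deliberately **not calibrated to any country's actual 2008 rates**.
Consequently all quantitative claims the tests make are *structural*
(conservation, round-trips, oracle equivalence, dominance directions,
frontier properties), not reproductions of any published national
estimate. A green suite establishes that the machinery is correct and
that the qualitative economics (what dominates, what is hopeless) fall
out of inputs with this shape; it does not establish Australian DALY
totals.

Risk factors are drawn independently within age/sex strata apart from
linear age drifts in blood pressure and cholesterol; real survey
correlations between factors are not emulated (a correlation structure
would sharpen the high-risk tail but leaves every tested property
unchanged).

## Choices made where the design was genuinely open

**Calibration.** Rather than refitting risk-equation coefficients, the
predicted risk is scaled per age band and sex so that its cell mean
matches the observed five-year first-event probability. The observed
probability is derived from annual incidence $\lambda$ net of competing
background mortality $m$ as
$P = \frac{\lambda}{\lambda+m}\bigl(1-e^{-5(\lambda+m)}\bigr)$, exact
under constant hazards. The scale acts on the probability scale with a
cap at 1; when the cap binds, the scale is found by bisection so the
cell-mean contract still holds (verified against a grid-scan oracle).
Because results flow only through calibrated risk, the placeholder
logistic coefficients need only produce realistic *gradients*, not any
published equation's values.

**Risk-factor → RR conversion is linear.** RR reduction = constant ×
percent change (3.4%/6.3% per 1% systolic BP, 1.8%/0.80% per 1% total
cholesterol), floored at RR = 0.01. A compounding variant would differ
only for implausibly large single-intervention changes; linearity matches
the per-1% phrasing of the underlying meta-analysis constants.

**Sodium.** Table effects are stored in mmol/day (a mg/day reading would
be physiologically negligible); a change in blood pressure is derived
first via age/sex slopes (0.025 mmHg per mmol/day at 35, rising with
age), then expressed as a percent of the cohort's baseline systolic
pressure.

**Behaviour-change effect retention 0.01.** The published structure this
package mirrors shows dietary advice, lifestyle programs, phytosterol
margarine and community heart programs achieving roughly *one percent* of
the population health gain their trial effect sizes would deliver if
fully sustained, at full delivery cost — which is why their
cost-effectiveness ratios sit near $1M/DALY while drugs with comparable
trial RRs sit near $10k/DALY. The library therefore carries an
`effect_scale = 0.01` for these four interventions (trial means are kept
verbatim; the scale is separate metadata), representing near-complete
long-run decay of behavioural effects at the population level. This is a
stated-world constant chosen once from that printed relationship, not a
fitted quantity.

**Adherence.** 40% of initiators discontinue after 12 months and are
charged no costs and receive no effect from year 2; year-1 costs are
charged to all initiators. Population-wide interventions are sustained
(no discontinuation) with ongoing delivery costs.

**Aspirin's harms.** The net stroke effect splits by subtype at the rate
level (ischaemic RR 0.86, haemorrhagic 1.32, default haemorrhagic
fraction 0.20 — configurable, as the split is not externally pinned);
GI bleeds are acute events with a per-event case fatality (default 0.05)
folded into the competing exit hazard, one-cycle disability and a
one-off treatment cost, not a persistent state.

**Markov conventions.** One-year cycles, no half-cycle correction
(a `half_cycle` switch exists but is off, matching a plain discrete-time
reading); occupancy and person-years are counted at cycle start; cohorts
enter at the five-year band midpoint. Disease states are
absorbing-while-alive (first-ever events only — this is primary
prevention), with configurable excess mortality (defaults 0.03/yr IHD,
0.06/yr stroke). Competing first events within a cycle use the
exponential formula, allocating the combined exit probability
proportionally to hazards — exact under constant hazards and testable
against path enumeration. Secular trend multipliers compound as
trend^(years since reference) on incidence and, by default, case
fatality. Simulation stops at extinction (alive < 1e−9 of the cohort) or
the age cap (110).

**Eligibility is fixed at baseline.** Cohorts do not migrate between
risk bands as they age; the band's mean relative risk (band mean ÷ cell
mean) multiplies CVD incidence for the whole simulation. Re-banding
during simulation would require risk-factor trajectories, which are out
of scope.

**Back-calculation.** Do-nothing incidence = observed incidence ÷
population-average *steady-state* (year-2+) effective RR of current
practice, per age band, sex and channel. Steady state is used because
observed rates reflect established practice, not an initiation year. The
round-trip (null → re-apply current practice → observed) is then exact
by construction, which is precisely the self-consistency the generalized
CEA framework demands.

**Costs.** Parenthetical cost values in the intervention table are
standard errors (per its footnote), so the government/patient split is a
separate configurable `patient_share` (default 0 for population-wide,
0.2 for primary-care interventions). Intervention costs are charged to
alive, covered persons in any alive state; disease costs charge incident
events a first-year cost and state occupants a subsequent-year cost.
"Other health care costs in added years of life" is an optional
per-life-year add-on, off by default.

**Current practice** (used only for back-calculation and as a comparator
scenario) is voluntary salt limits population-wide plus BP-lowering,
lipid-lowering and dietary advice offered across the ≥5% bands with
uptakes 0.35 / 0.25 / 0.20 of the primary-care reach (GP attendance 0.85
× assessment participation 0.70). These uptakes are stated-world choices
at the scale of typical preventive-treatment prevalence.

**Expansion pathway.** Each step re-simulates the full model for
package ∪ {candidate} and differences totals, so multiplicative-RR and
shared-population interactions are captured exactly (this is what makes
a candidate's incremental gain smaller than its standalone gain).
Cost-saving candidates are added first (ordered by health gain), then
lowest incremental ICER; ties break by gain then label, which makes the
path invariant to candidate order. Mutual exclusivity is configuration,
not inference: at most three of the four BP drug classes per band (the
beta-blocker is the displaced fourth), dietary advice vs lifestyle
program, and aspirin standalone-only (capacity 0) because its bleed
harms make it unattractive once better drugs occupy the package.
"Added to the package" conditions on the package as of that step.

**PSA.** RRs are drawn lognormal (moment-matched to mean/SE), percent
effects normal, sodium effects normal truncated at 0, costs gamma;
parameters are independent except shared ones (the statin trial RR reused
by current-practice lipid-lowering) drawn once per iteration. The
epidemiology and weights are held fixed — uncertainty propagation covers
intervention parameters only. ICER point estimates are mean-based for
deterministic tables and medians of draw-wise ratios under PSA; draws
with non-positive gain are handled on the net-monetary-benefit scale in
the frontier, avoiding ratio instability. The acceptability frontier
reports, per threshold λ (grid 0–150,000 by 1,000), the probability that
the deterministically optimal package maximises λ·gain − net cost.

## Numerical conventions

Discounting divides cycle *t* (0-based from the 2008 reference year) by
(1.03)^t; rate 0 is the plain sum. DALY-framework weights are
(1 − background disability) × (1 − state disability); QALY weights are
background utility × state utility, with matched defaults
(utility = 1 − disability) so the two metrics coincide unless the user
supplies elicited utilities. Tolerances used in the contracts: calibration
cell means to 1e−9; transition rows sum to 1 to 1e−12; ≤3-cycle
enumeration equivalence to 1e−12; back-calculation round-trip to 1e−9.

## Known limitations

* Cohort (not individual) simulation: within-band risk heterogeneity is
  collapsed to the band mean relative risk.
* No recurrent events or secondary-prevention pathway beyond disease-state
  costs and excess mortality.
* Non-CVD benefits of behaviour change (smoking, physical activity) are
  not modelled, understating those interventions' total value.
* PSA does not propagate epidemiology or weight uncertainty.
* The synthetic world's absolute DALY and dollar totals are illustrative;
  only their structure and ordering are load-bearing.
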