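---
title: "A Markov cohort model for the cost-utility of bariatric surgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for the cost-utility of bariatric surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baricea)
```

## The decision problem

Severe obesity raises the risk of type 2 diabetes (T2D) and cardiovascular
disease and lowers health-related quality of life. Bariatric surgery —
gastric bypass (GBP), sleeve gastrectomy (SG) or adjustable gastric banding
(AGB) — produces large, durable weight loss, frequent diabetes remission
and lower blood pressure, at the price of an up-front tariff, perioperative
risk and long-term follow-up. `baricea` implements a decision-analytic
state-transition (Markov) cohort model that weighs these against
conventional medical management (CMM) from a health-care payer
perspective, in 2012 euros, producing discounted costs, life years (LY),
quality-adjusted life years (QALYs), incremental cost-effectiveness ratios
(ICERs) and dominance verdicts at a 10-year and a lifetime horizon.

## Model structure

The cycle length is one month. A living state is the combination of

* a **treatment track** — CMM; post-surgery without or with a chronic
  surgical complication; or post-conversion (AGB revised to bypass);
* a **diabetes status** — none, established T2D, or remission (surgery
  only);
* a set of established **cardiovascular conditions** out of angina,
  post-myocardial-infarction (MI), stroke, heart failure (HF) and
  peripheral artery disease (PAD), capped at two concurrent conditions.

Stroke is costed with two one-year tunnels: month counters 1–12 carry the
first-year annual cost, 13–24 the second-year cost, after which a chronic
post-stroke state retains the year-2 cost (the model's stated assumption —
only the first two years are separately priced). Tunnel progression is
forced: no self-loop exists inside the tunnel, which the test suite checks
on the transition matrix. Transient ischemic attack (TIA) is an *event*,
not a state: each occurrence charges a one-time cost and one month of
disutility. Death is split into a cardiovascular state (fed by acute case
fatality of MI and stroke and by the chronic excess mortality of
established conditions and diabetes) and an other-cause state (fed by
background mortality and perioperative deaths). With the default
configuration this enumeration yields `r build_state_space()$n` states.

At the comorbidity cap, further incident events are suppressed rather than
tracked; with the default cap of two this affects only the small mass that
already carries two conditions. Conversion surgery moves AGB-effect mass
to a post-conversion track that follows the bypass efficacy curve indexed
from the original surgery month; a cohort model cannot track per-slice
conversion dates, so the trajectory clock is *not* reset, and a
complication flag is not carried through conversion.

### Transition probabilities

Within a cycle, exits are assembled from independent per-event monthly
probabilities; if their sum ever exceeded one, the row would be
renormalised and the event counted (with the packaged inputs this does not
occur). The engine propagates the cohort with a precomputed edge list and
per-cycle vectorised probability filling; an explicit dense transition
matrix built from the same probabilities is available, and the two paths
agree to below 1e-12 in the tests. Row stochasticity is property-tested
under random parameterisations, and mass conservation holds to 1e-9 over a
lifetime run.

The surgery cycle composes an instantaneous routing — 30-day mortality,
then the complication split — with the normal monthly dynamics, so the
surgical arm is not granted an event-free month. Perioperative severe
adverse events are costed on the operated flow without a state change.

### Risk equations (synthetic placeholders)

Cardiovascular risk depends on age, sex, systolic blood pressure (SBP),
BMI, diabetes and smoking through a Framingham-style logistic equation on
the annual scale, converted to monthly via the constant-rate convention
`1 - (1 - p)^(1/12)`. The true coefficients of the source model live in
unprinted literature, so the packaged coefficients are documented
synthetic placeholders: fixed, literature-plausible slopes with intercepts
solved so that the reference cohort (age 40.4, 26.3% male, SBP 140.1, BMI
48.8, 20.6% diabetic, 21.9% smoking) matches static-cohort equivalents of
10-year risk anchors (3% angina, 6% MI, 3% stroke, 3% HF, 3% PAD, 0.5%
TIA, case fatality 1.7% for MI and 16% for stroke). Only
order-of-magnitude calibration is claimed; `calibration_report()` prints
the per-event ratio of model to anchor risks rather than asserting it.
Because the cohort ages and accumulates comorbidity, dynamic 10-year risks
sit somewhat above the static anchors (and the TIA counter records
events, not first events, so it can exceed a per-person risk); the
acceptance surface binds only the diabetes risk (within ±50% of 0.23) and
the direction of every surgery/CMM relative risk.

BMI can enter the risk equations continuously (per kg/m² above 25, the
default) or by WHO class midpoints. The source description names "BMI
category", but the subgroup grid it reports contains baseline BMIs 42 and
52, which share a WHO class: category entry would give both cohorts the
same cardiovascular risk reduction and invert the published monotone
cost-effectiveness gradient in baseline BMI, so the continuous mode is the
default and the category mode a configuration option.

Established conditions multiply the annual risks of other events (generic
relative risk 1.5; HF→stroke 2.0) and background mortality (per-condition
multipliers 1.2–2.5, T2D 1.5). Diabetes incidence is log-linear in BMI
above 25 kg/m² (RR 1.09 per unit), suppressed in remission, with
re-incidence at the current-BMI rate. Remission is a step schedule: a high
annual probability (0.55) in the first post-operative year, 0.03
thereafter, zero under CMM.

### Background mortality

The background life table is synthetic: a Gompertz–Makeham hazard
(`a + b c^age`, defaults a = 2e-4, b = 2.8e-5, c = 1.1; male hazard 1.6×
female) closed at age 110, giving a life expectancy at birth of about 79
years (female) and 74 (male). The fraction of all-cause mortality
attributable to ischemic heart disease rises sigmoidally with age towards
a 15% plateau and is *subtracted* before use, because coronary deaths are
generated explicitly by the model; charging both would double-count. A
loader for real period tables in the same four-column text layout is
provided.

### Risk-factor trajectories

Surgery reduces BMI linearly over twelve months to a procedure-specific
fraction of the pre-operative level (GBP 32%, SG 28%, AGB 18% — synthetic
registry-plausible values), then partially regains along piecewise-linear
anchors (fraction of the 12-month loss retained: 95% at year 2, 72% at
year 10, 70% at year 15), constant after 15 years until death. The CMM
arm follows a configurable drift (default 0). SBP falls by a configured
12-month delta (−4.5 mmHg non-diabetic, −10 diabetic) and stays there.
The `mix` procedure is the share-weighted combination of the three
procedures (registry shares 51/17/33, normalised), which for these
piecewise-linear forms equals the weighted average of the three
trajectories exactly.

## Economics

Annual state costs (T2D €3867; stroke tunnels €5493/€6268; post-MI €7056;
HF €5393; PAD €2897; angina €3899) accrue as occupancy × cost/12; acute
MI (€7644), acute stroke (€4054), TIA (€3327), severe adverse events and
conversions are one-time costs on the event flows; the procedure tariff
(€8104 GBP/SG, €5621 AGB, mix-weighted) is charged on the operated flow.
The published visit schedule is followed (pre-operative surgeon ×2 +
dietician + psychologist; two surgeon and a nurse visit in the first
post-operative month; a surgeon visit at one year; an annual dietician
consultation from year two; annually a GP and dietician visit under CMM)
with synthetic unit costs, since the source prints the schedule but not
the prices.

Utility is additive with a floor at zero: an age-declining baseline
(0.97 at age 20, −0.002/year), −0.005 per BMI unit above 25, −0.07 for
T2D (lifted in remission), condition decrements (angina 0.09, post-MI
0.06, stroke 0.15, HF 0.12, PAD 0.06), −0.02 for the chronic complication
state and a one-month −0.05 per TIA. Dead states contribute nothing.

Discounting is 3% annually with costs and outcomes beyond the first year
discounted: cycles 1–12 carry factor 1 and cycle t > 12 carries
`1.03^(-floor((t-1)/12))`; smooth monthly compounding is available behind
a flag. The dominance verdict table is exhaustive over the nine sign
combinations of (ΔC, ΔQALY), with weak dominance on the zero-cost
boundary and the ICER reported only when both increments share a nonzero
sign; cost-effectiveness at the €35,000/QALY threshold is judged by the
incremental net monetary benefit.

## Sensitivity analysis

One-way analysis perturbs each parameter across its configured range
(binary cohort flags to exactly 0 and 1) on the standard one-way cohort
(40.4-year-old male, BMI 48.8, non-smoking, diabetes-free), reporting the
ICER where defined at the base and both bounds and the net monetary
benefit otherwise, with a €100 swing threshold for the headline tornado.
The probabilistic analysis draws every distribution-carrying,
non-excluded parameter independently (reimbursement tariffs are held
fixed), re-runs the full comparison per iteration, and classifies each
iteration as cost-saving, cost-effective at the threshold, or neither;
one master seed derives a deterministic per-iteration seed stream so any
single iteration is replayable. Collapsing all distributions to point
masses reproduces the deterministic base case bit-for-bit, which the
tests assert.

## Scenarios

Delayed surgery keeps the cohort under CMM dynamics for 1–3 years —
accruing events, costs and deaths — and then operates on the survivors at
their evolved BMI/SBP and condition mix, charging the (discounted) tariff
at the delay boundary. The subgroup batch runs the 2 × 4 × 2 grid of
41-year-old non-smoking males and females at baseline BMI 33/37/42/52
with and without T2D, reporting both horizons from a single lifetime run
per cohort.

## Problem sizes and reproducibility

The test suite exercises mostly 10-year (120-cycle) and 24-cycle runs,
with single lifetime runs for mass-conservation and delay properties, and
small probabilistic batches (up to 200 iterations at short horizons);
`scripts/acceptance.R` runs the full base case, the 16-cohort batch, the
delay scenarios and a 200-iteration lifetime probabilistic analysis.
These sizes are the package's reporting choices; the functions default to
the reference analysis sizes (e.g. 5000 iterations). Every stochastic
entry point takes an explicit seed, and run manifests (seed, config hash,
package version) make outputs reproducible.

## What the synthetic data can and cannot show

The synthetic life table, risk coefficients, visit prices, utility
decrements and trajectory anchors emulate the *kind* of inputs the real
analysis drew from national statistics and literature, at realistic
orders of magnitude — they are not those inputs. Passing tests therefore
demonstrate that the machinery is correct (arithmetic, conservation,
monotonicity, reproducibility, the published worked examples that are
pure arithmetic) and that the model reproduces the qualitative published
findings (lifetime dominance, larger gains at higher baseline BMI and
with baseline diabetes, clinical losses under delayed surgery, a high
cost-saving fraction under parameter uncertainty). Absolute euro and QALY
totals depend on the placeholder inputs and should not be read as
estimates for any real population; substituting study-specific
coefficients and tariffs via the YAML configuration is the intended use.

## Known limitations

* Cohort (not individual) simulation: no per-person event histories; the
  conversion clock cannot be reset per converted slice.
* Musculoskeletal, gynecological and cancer complications of obesity are
  not modelled.
* Only direct medical costs; no indirect/societal costs, no re-inflation
  of the 2012 euro prices.
* Smoking and sex enter as cohort fractions; single-sex or
  smoker-stratified cohorts should be run as separate profiles.
* No half-cycle correction: with monthly cycles the bias is far below the
  parameter uncertainty.
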