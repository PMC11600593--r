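---
title: "A hybrid decision-tree and Markov model for first-line cryoballoon ablation in paroxysmal AF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid decision-tree and Markov model for first-line cryoballoon ablation in paroxysmal AF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afcem)
```

## The decision problem

Symptomatic paroxysmal atrial fibrillation (PAF) can be managed first-line
either with antiarrhythmic drugs (AADs) or with pulmonary vein isolation by
cryoballoon catheter ablation. Ablation costs more up front but reduces
arrhythmia recurrence, the need for repeat procedures, and time spent in
symptomatic AF states that carry utility decrements and elevated stroke and
heart-failure risk. `afcem` implements a cohort-level cost-effectiveness
model of this trade-off from a German statutory payer perspective: costs in
2023 euro, health benefit in quality-adjusted life years (QALYs), both
discounted at 3% per annum, with a willingness-to-pay (WTP) threshold of
EUR 35,000 per QALY.

The headline quantities are the incremental cost-effectiveness ratio
$\mathrm{ICER} = \Delta C / \Delta E$ and the net monetary benefit
$\mathrm{NMB} = \lambda\,\Delta E - \Delta C$ at WTP $\lambda$, where
$\Delta C$ and $\Delta E$ are per-patient discounted lifetime differences
(cryoablation minus AAD).

## Model structure

The model is a hybrid of a one-year decision tree and a 40-year Markov
cohort model with a three-month cycle, matching the follow-up of the
first-line ablation trials in year one and a lifetime horizon thereafter.

**States.** Five rhythm states: normal sinus rhythm (NSR; no AF recorded
within a three-month cycle), short-term (ST) episodic AF, long-term (LT)
persistent AF, permanent AF, and death. NSR, ST-episodic and LT-persistent
each carry four substates $k \in \{0,1,2,3\}$ counting repeat ablations
received, because the relative risk (RR) of symptom recurrence and
resolution depends on the number of procedures. At most three total
procedures are allowed, including the cryoablation arm's index procedure
(which counts toward the cap but not toward $k$). Death is reachable from
every living state; no transition reduces $k$; permanent AF admits no exit
but death.

**Decision tree (year one).** The whole cohort (1,000 persons, baseline age
57.5) enters symptomatic. The cryoablation arm receives the index procedure
at entry: its cost is charged undiscounted at time zero, and the cohort
starts in `NSR_0` with the ablation success probability (defined as return
to NSR for the following 90-day cycle), otherwise `ST_0`. The AAD arm
enters `ST_0` on drug therapy and reaches NSR through resolution. The tree
then evaluates four quarterly periods with exactly the Markov engine's
transition machinery — recurrence, resolution, re-ablation and death, with
progression to the chronic states disabled — so tree and Markov logic
cannot drift apart. The end-of-year occupancy over `NSR_k`, `ST_k` and
death is the initial Markov allocation. Where the trials' exact baseline
state distribution would be needed, the initial AF fraction is a
configuration field (default 1).

**Markov phase.** 160 quarterly cycles. Within a cycle, death acts first as
a competing risk; rhythm and ablation transitions apply to survivors.
Re-ablation moves `ST_k`/`LT_k` to `NSR_{k+1}` with probability
(re-ablation rate × ablation success) and to `ST_{k+1}` on failure, only
while total procedures remain below three. Recurrence and resolution
probabilities are the arm-specific base probabilities multiplied by the
ablation-count RRs and capped into $[0,1]$; if competing outflows of a
state ever exceed one they are renormalised proportionally and the event is
reported. The cohort ages deterministically,
$\mathrm{age}(t) = 57.5 + 0.25\,t$.

## Clinical events and mortality

Stroke incidence is annual, indexed by the cohort's CHA2DS2-VASc score
(baseline configurable, +1 at age 65 and again at 75) and multiplied by a
health-state RR; heart-failure incidence is annual by age band with an RR
above one only in permanent AF. Annual probabilities convert to quarterly
ones by the complement-power rule $p_c = 1-(1-p_a)^{1/4}$, which recovers
the annual probability when compounded over four cycles.

The mortality contract combines, on the hazard scale, (i) sex-weighted
cause-deleted background mortality from an annual life table,
(ii) stroke-attributable mortality as stroke incidence hazard × 30-day case
fatality among the stroke-naive, and (iii) heart-failure excess mortality
weighted by HF prevalence. The combined annual probability is converted to
the quarterly cycle. In the no-event limit this conserves the life table's
survivor curve exactly (a tested invariant). The exact published
combination formula is not available; this additive-hazard form is the
standard construction and is the module's defining contract.

**Sequelae.** Prior stroke (by severity: non-disabling, moderate, severe)
and prevalent heart failure (by NYHA class) are tracked as prevalence
masses rather than by expanding the state space: the engine propagates
per-state "stroke-naive" and "HF-free" masses with the same survivor
matrices it applies to occupancy, so the cohort recursion is the exact
expectation of the individual-level process that the microsimulation
oracle samples (see below). Severity/NYHA composition of the prevalent
masses equals the incident split because case fatality and attrition do
not differ by severity class. Event-attributable mortality is applied
through the state-level prevalence-weighted hazard — a mean-field
convention mirrored exactly by the microsimulation.

## Costs, utilities, accrual

Unit costs (2023 euro) follow the published base case: ablation procedure
8,121; CV hospitalisation 1,464; emergency visit 32; outpatient visit 107;
pharmacological/electrical cardioversion 1,206/166; acute stroke by
severity 1,204/2,864/5,168 plus 391 per cycle long-term; heart failure
166–291 per cycle by NYHA class; arm-specific pharmacy 69 (cryoablation)
vs 89 (AAD) per person-cycle. Healthcare-contact costs are expected
per-cycle utilisation rates (by state and arm) times unit costs, applied
to everyone alive in the state; procedure costs are event-driven; acute
stroke costs are charged once in the event cycle and the long-term cost
every subsequent cycle to survivors.

QALYs accrue as cycle length × occupancy × utility, where utility is a
sex-weighted baseline norm declining linearly with age minus the rhythm
state decrement (ST-episodic 0.08, LT-persistent 0.08 by assumption equal
to ST, permanent 0.11) minus long-term adverse-event decrements on the
prevalent masses, floored at zero per state; short-term stroke decrements
apply in the event cycle. Decrement arithmetic is additive — the source is
silent on the combination rule.

Discounting uses $(1+r)^{-0.25 t}$ from model entry with $t$ the 0-based
global cycle (the tree occupies cycles 0–3), so cycle 160 carries
$1.03^{-40}$. No half-cycle correction is applied — the original model is a
spreadsheet construction and states none — but a configuration switch
(`settings.half_cycle_correction`) exposes it for sensitivity work.
Within year one the entry procedure at $t=0$ is undiscounted and the four
quarterly cycles are discounted continuously from time zero; the source is
silent and this is consistent with the lifetime rule.

## Blanking period

Clinical consensus treats AF episodes within 12 weeks of ablation as
transient ("blanking"); the base case counts them (full healthcare
utilisation is captured), and a scenario explores discounting them. When
active, recurrences arising from mass ablated in the immediately preceding
cycle — including the index procedure for the first tree period — are
returned to NSR accounting; the episode's ST-state utilisation costs still
accrue (the assumption extends to cardioversion costs, which the source
leaves unstated). A tested property: blanking never increases year-one
ST-episodic occupancy.

## Scenario analyses

`builtin_scenarios()` provides the seven deterministic scenarios: blanking
period on; recurrence RRs (counts 1–3) +10%; resolution RRs +10%; ablation
success −30% proportionally; stroke incidence −30% proportionally;
literature-sourced health-state stroke RRs (config-supplied, synthetic
default, because the published source table is unavailable); permanent-state
heart-failure RR +10%. Scenario overrides are pure transformations
(set / multiply / toggle on dot-paths), so the base parameter set is never
mutated.

## Probabilistic sensitivity analysis

Gamma distributions (moment-matched: shape $m^2/s^2$, scale $s^2/m$) are
used for costs, relative risks and utilisation rates; beta distributions
(moment-matched via $\nu = m(1-m)/s^2 - 1$) for probabilities and utility
quantities. Expert-estimated scalars carry a 10% relative standard error.
The four base recurrence/resolution probabilities are drawn jointly on the
logit scale through a lower-triangular Cholesky factor standing in for the
unavailable regression variance-covariance matrix; the factor is a
configuration input produced by the synthetic generator. Severity and NYHA
splits are sampled component-wise and renormalised to the simplex, and the
LT-persistent decrement stays tied to the ST-episodic one. One root seed
spawns per-iteration substreams, so results are bit-reproducible; with all
standard errors zero and a zero-scale coefficient block every iteration
reproduces the deterministic run (a tested cross-module identity).
Summaries: means, empirical 2.5/97.5-percentile credible intervals, the
mean ICER as the ratio of mean increments (per-iteration ICERs are
unstable around $\Delta E = 0$), probability of cost-effectiveness at the
WTP, probability of cost saving, and the cost-effectiveness acceptability
curve (CEAC). The configured default is 5,000 iterations.

## Synthetic inputs and calibration

The per-cycle transition probabilities, utilisation rates, stroke/HF
incidence curves, utility norms and the life table were estimated in the
original analysis from individual patient data that are not public. The
`synthetic_inputs` module therefore generates stand-ins with the right
qualitative structure: an arm effect as a recurrence hazard ratio below
one, recurrence RR decreasing with ablation count, higher AAD-arm
re-ablation uptake, Gompertz background mortality
$q(a) = 1-\exp(-\alpha e^{\beta a})$ with sex-specific $\alpha$. Default
magnitudes were fixed once so the base run lands in the regime the
published analysis reports — cryoablation slightly costlier overall with a
QALY gain, roughly one re-ablation avoided, and close to half the AF-state
time — with unit costs at their printed values and utilisation rates at
magnitudes consistent with the printed lifetime healthcare-contact costs.
Every synthetic quantity is flagged in `params$meta$placeholders` and
logged at run time.

What the generator does **not** emulate: real trial event-time
heterogeneity, patient-level covariates beyond the sex weighting,
correlation between utilisation and rhythm history, or the published
supplementary rate tables themselves. Passing tests therefore demonstrate
the correctness of the model machinery under the stated contracts, not
numerical reproduction of the published cost-effectiveness results, whose
inputs are unavailable.

`calibrate()` is a deliberately explicit coordinate search: the caller
names the free parameter paths and the targets (e.g. lifetime re-ablation
counts, time in ST-episodic, AF-time reduction); the routine
multiplicatively perturbs one parameter at a time, halving its step when
no move improves the summed normalised deviation, and never returns a
worse set than its input. Automatic free-parameter selection is avoided so
that the stand-in cannot silently overfit.

## Numerical choices

* Conservation is enforced to 1e-9 on occupancy rows (tested to 1e-12 in
  the tree); probability caps renormalise proportionally and are reported.
* Ablation counts are structural: totals are capped at three by removing
  re-ablation flows, so expected counts cannot exceed the cap.
* Degenerate inputs (all-dead allocations, zero probabilities, zero
  costs, empty scenario lists) pass through as exact fixed points.
* JSON serialisation uses 17 significant digits so save/load round trips
  are lossless; the run manifest records an MD5 of the config file.
* Tie-breaks: LT-persistent remission to ST is off by default
  (configurable); heart-failure decrements apply from onset.

## Verification strategy and problem sizes

The package checks itself at three levels. Arithmetic identities
(probability conversions, discount factors, moment matching) are tested
against closed forms. The cohort engine is cross-checked against an
independent individual-level microsimulation of the same stochastic
process (`run_microsim()`): the suite runs 100,000 walkers over the full
164-cycle horizon on three synthetic parameter sets and requires
occupancy, cumulative events and accruals to agree within three
Monte-Carlo standard errors. The PSA is checked by degeneracy (zero
standard errors reproduce the deterministic run to 1e-9 relative at 100
iterations) and by distributional moment recovery at 1e5 draws. Routine
test runs use these sizes — large enough for the Monte-Carlo bounds to be
sharp, small enough to keep the suite fast; `scripts/acceptance.R`
recomputes the headline quantities with a 500-iteration PSA.

## Limitations

Recurrent strokes, anticoagulation effects and bleeding events are not
modelled; sequela masses use the mean-field mortality convention described
above; the societal perspective (productivity, informal care) is out of
scope; and all trial-derived magnitudes are synthetic stand-ins — results
from the packaged defaults characterise the model, not German clinical
reality.
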