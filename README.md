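# afcem

A cost-effectiveness model of first-line **cryoballoon catheter ablation**
versus **antiarrhythmic drug (AAD) therapy** for symptomatic paroxysmal
atrial fibrillation (PAF), from a German statutory payer perspective. The
package is aimed at health-economic modellers who want a fully tested,
scriptable implementation of this class of hybrid decision-tree + Markov
cohort models — including probabilistic sensitivity analysis, scenario
analysis, an individual-level microsimulation cross-check and a synthetic
input generator — rather than a spreadsheet.

## The model in brief

A one-year decision tree allocates a cohort of 1,000 untreated symptomatic
PAF patients (baseline age 57.5) to normal sinus rhythm (NSR), ST-episodic
AF or death; a Markov model with three-month cycles then follows the
cohort for 40 years over 14 states — NSR, ST-episodic and LT-persistent AF
(each with re-ablation substates k = 0..3), permanent AF and death, with
at most three total ablation procedures. Stroke (CHA2DS2-VASc-indexed) and
heart failure feed costs, utility decrements and an additive-hazard
mortality combination on top of a cause-deleted life table. Costs (2023
EUR) and QALYs are discounted at 3% per annum and compared at a
willingness-to-pay (WTP) of EUR 35,000 per QALY:

    ICER = ΔC / ΔE        NMB = WTP × ΔE − ΔC

The probabilistic sensitivity analysis samples costs from moment-matched
gamma distributions, probabilities and utilities from beta distributions,
and the base transition probabilities jointly via a Cholesky-factored
coefficient block, and reports means, 95% credible intervals, the
probability of cost-effectiveness and the acceptability curve (CEAC).

Because the trial-derived inputs behind the original analysis are not
public, all transition probabilities, event-rate curves, utility norms and
the life table ship as clearly flagged synthetic stand-ins (see
`vignette("cost-effectiveness-model")`), while unit costs and utility
decrements carry their published values.

## Worked example

```r
library(afcem)

params <- af_parameters()          # packaged synthetic base case
cea <- run_cea(params)             # decision tree + Markov, both arms
glance(cea)
#>   cost_cryoablation cost_aad qaly_cryoablation qaly_aad delta_cost delta_qaly  icer dominance  nmb
#> 1             19226    18965              13.4     13.2        261      0.182  1432      none 6119
```

Cryoablation costs EUR 261 more per patient over a lifetime but yields
0.182 extra QALYs, an ICER of roughly EUR 1,430 per QALY — far below the
EUR 35,000 threshold, hence a positive net monetary benefit of about
EUR 6,100. The supporting detail is tabular throughout:

```r
tidy(cea)                          # per-arm cost breakdown by category
cea$ablations                      # re-ablations: 0.26 (cryo) vs 1.20 (AAD)
cea$state_time                     # years per rhythm state (48% less AF time)
cea$event_metrics                  # lifetime stroke/HF rates, NNT, cost per event avoided

psa <- run_psa(params, n_iterations = 500, seed = 1)
glance(psa)                        # means, 95% CrIs, P(cost-effective) = 99.8%
autoplot(psa)                      # cost-effectiveness plane
plot_ceac(psa)                     # acceptability curve

cem_scenarios(params, "out/")     # base case + the seven built-in scenarios
```

A thin command-line front-end wraps the same functions:

```sh
Rscript inst/cli/afcem.R synth-init --out cfgdir --seed 1
Rscript inst/cli/afcem.R run  --config cfgdir/config.json --out results/
Rscript inst/cli/afcem.R psa  --config cfgdir/config.json --out results/ --psa-iterations 5000 --seed 1
```

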