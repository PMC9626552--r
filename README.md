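# nmpmito

Mitochondrial bioenergetics of donor livers during normothermic machine
perfusion (NMP).

## The problem

Livers accepted for transplantation after NMP are currently selected on
perfusate chemistry (lactate clearance, pH stability, transaminase
release). Mitochondrial function is the upstream quantity those markers
proxy: a graft that cannot couple respiration to ATP synthesis fails even
when its enzymes look acceptable. This package implements an end-to-end
pipeline for quantifying that bioenergetic competence from high-resolution
respirometry (HRR) of serial liver biopsies, and for relating it to
post-transplant outcome:

1. **Trace analysis** — closed-chamber oxygraph recordings (oxygen
   concentration at a 2 s interval, 2 mL chamber, 1 mg wet tissue per mL)
   are converted to steady-state mass-specific fluxes per SUIT
   (substrate-uncoupler-inhibitor titration) step:
   `J(t) = (-dC/dt * 1000 - Jbg(C)) / rho` in pmol O₂ s⁻¹ mg⁻¹, with a
   deterministic plateau detector and duplicate-chamber merging.
2. **Coupling control** — succinate-pathway coupling states L (LEAK), P
   (OXPHOS), P꜀ (after cytochrome *c*), E (ET capacity, max over CCCP
   steps) and the control efficiencies
   *P-L* = 1 − L/P (ATP-production efficiency),
   cytochrome *c* = 1 − P/P꜀ (outer-membrane damage),
   *E-P* = 1 − P/E (phosphorylation-system control), plus flux control
   ratios FCR = J_pathway / J_ref.
3. **Adenylate energetics** — ATP:ADP and the energy charge
   (ATP + ½ADP)/(ATP + ADP + AMP).
4. **Perfusate viability** — the transplantability rules: lactate ≤ 2.5
   mmol L⁻¹ by 2 h, pH 7.30–7.45 without repeated bicarbonate, and
   AST/ALT/LDH ≤ 20,000 U L⁻¹.
5. **Outcome model** — trapezoidal AUC of each biomarker over the first
   6 h of NMP, bidirectional stepwise-AIC term selection with a marginality
   (hierarchy) rule, OLS with Type II ANOVA, standardized betas and partial
   residuals against the L-GrAFT early-graft-function score.

The clinical cohort behind the published analysis is not deposited, so the
package ships a **synthetic-data generator** whose defaults encode the
published summaries (lognormal fluxes at the printed medians/IQRs, beta
efficiencies at means 0.8 / 0.06, an outcome linearly linked to the AUC
biomarkers with the published coefficient signs). Every downstream stage is
tested against this generator's known ground truth.

## Worked example

```r
library(nmpmito)

# simulate a SUIT02 run at the published cold-storage coupling states
p <- trace_sim_params(
  true_fluxes = c(LEAK = 8.21, OXPHOS = 40.49, OXPHOS_cytc = 43.48,
                  CCCP1 = 65, CCCP2 = 70.33, CCCP3 = 68),
  noise_sd = 0.2, seed = 11
)
cfg <- flux_extraction_config(smoothing_halfwidth = 15, cv_max = 0.3,
                              slope_tolerance = 0.2)
tbl <- evaluate_protocol(simulate_trace(p), suit_protocol("SUIT02"), cfg)
cs  <- coupling_states(tbl)
cs
#> <coupling_profile> S-pathway: L=7.90 P=40.36 Pc=42.31 E=70.44
pl_control_efficiency(cs$L, cs$P)
#> [1] 0.8042544
cytc_control_efficiency(cs$P, cs$Pc)
#> [1] 0.04619117
```

The extracted states land within a few percent of the generator truth; the
P-L control efficiency of 0.80 says 80% of OXPHOS-state respiration is
coupled to phosphorylation (an intact inner membrane), and the cytochrome
*c* efficiency of 0.05 says exogenous cytochrome *c* barely stimulates
respiration (an intact outer membrane).

The full workflow — cohort simulation, flux extraction, coupling and
adenylate summaries, viability decisions, and the stepwise/Type II outcome
model — is laid out as numbered drivers under `analysis/`
(`Rscript analysis/01_simulate_cohort.R`, …), each writing its tables to
`results/`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline's anchor quantity from scratch: it simulates 50
noisy SUIT02 oxygraph traces at the published cold-storage step fluxes,
extracts the LEAK and OXPHOS plateaus from the raw concentration traces,
applies the P-L control efficiency, and writes the result as JSON.
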