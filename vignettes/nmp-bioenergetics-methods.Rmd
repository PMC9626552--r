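---
title: "Methods: liver NMP bioenergetics, from oxygraph traces to outcome model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: liver NMP bioenergetics, from oxygraph traces to outcome model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmpmito)
```

This vignette is the package's own account of its models and numerical
choices: what is computed, under which assumptions, which defaults matter,
and what a green test does and does not establish.

## 1. The measurement model

A closed-chamber oxygraph records oxygen concentration $C(t)$ (µM) every
2 s in a 2 mL chamber holding liver homogenate at $\rho = 1$ mg wet mass
per mL. Tissue respiration removes oxygen, so the mass-specific flux is
recovered from the local derivative,

$$ J(t) \;=\; \frac{-\,\dot C(t)\cdot 1000 \;-\; J^\circ_{bg}(C)}{\rho}
\quad [\text{pmol O}_2\, \text{s}^{-1}\, \text{mg}^{-1}], $$

with an instrumental background $J^\circ_{bg}(C) = a + bC$ per mL
(defaults $a=b=0$, which keeps toy cases closed-form; the simulator can
inject nonzero values). A SUIT (substrate-uncoupler-inhibitor titration)
protocol is an ordered sequence of chamber additions; between additions
respiration settles to a steady state, so the trace is
plateau-then-titrate: piecewise-linear decline with a transient after each
event.

**Derivative estimation.** $\dot C$ comes from a windowed local linear
regression (default half-width 5 samples ≈ 10 s) rather than a finite
difference; at 2 s sampling a finite difference amplifies recording noise
by $1/\Delta t$. Edge samples with truncated windows are flagged and
excluded from plateau windows.

**Plateau detection.** After each event the detector skips
`skip_after_event` (60 s), then scans windows of `window_length` (120 s),
accepting the earliest one whose fitted flux drift is ≤ 1% of the flux per
minute and whose coefficient of variation is ≤ 5%. If nothing qualifies
before the next event (or `max_wait` = 600 s) the step is flagged
`no_plateau`; a window running past the trace end is flagged
`short_window`. Both flags still report a value — flags annotate, they
never silently censor.

**Plateau statistic.** The step flux is the **10% trimmed mean** of the
window fluxes. A median was considered: it is equally robust to the
decaying titration transient, but under white recording noise the local
slope estimates entering the window are individually very noisy, and the
median of such a window carries roughly four times the standard deviation
of the window mean. The trimmed mean keeps the robustness while staying
near the efficiency of the mean; with it, the Monte-Carlo recovery checks
below pass with their stated margins, which the median cannot achieve at
any window length that fits a titration step.

**Noise-adapted settings.** The variance of a regression slope over a
window of $n$ samples at spacing $\Delta t$ with noise $\sigma$ is
$\sigma^2 / \sum (t_i - \bar t)^2 \approx 12\sigma^2 / (n^3 \Delta t^2)$.
At $\sigma = 1$ µM this floor is ~0.9 pmol s⁻¹ mL⁻¹ for a 300 s window —
an irreducible ~11% per-run scatter on a LEAK flux of 8.21. Consequences
drawn *a priori* from this arithmetic:

* recovery of the low LEAK flux needs the longest window the protocol can
  afford (a 900 s LEAK step, 600 s window in the recovery experiments);
* the default CV gate (5%) is meaningful only for low-noise traces; noisy
  analyses must relax it (the gate then merely picks the earliest window)
  and widen the derivative half-width (15 samples);
* claims about extraction accuracy at 1 µM noise are claims about the
  **Monte-Carlo mean** across seeds, never about single runs.

## 2. Coupling control

From a SUIT02 step table the coupling states are L (LEAK: succinate +
rotenone, no ADP), P (OXPHOS: saturating ADP), P꜀ (after exogenous
cytochrome *c*) and E (electron-transfer capacity). E is the **maximum**
over the stepwise CCCP titrations: uncouplers are titrated until
respiration peaks, and an overshooting final step must not lower E.

Efficiencies: $1 - L/P$ (P-L control; ATP-production efficiency),
$1 - P/P_c$ (cytochrome *c* control; outer-membrane damage), and the E-P
control with **both conventions implemented** — variant A $= 1 - P/E$ and
variant B $= 1 - P_c/E$ — because the literature uses both and they differ
by ~0.03 at typical values (0.42 vs 0.38 at the worked states used
throughout this package). Variant A is the default; both are always
reported. Negative efficiencies are returned **unclipped with a warning**:
they diagnose titration failures (e.g. CCCP overshoot past the optimum)
that clipping would hide.

Cohort summaries are **summary-of-ratios** (median/mean of per-liver
efficiencies), not ratio-of-summaries; the two differ in skewed cohorts
and only the former respects per-liver pairing.

Flux control ratios normalize the OXPHOS-state pathway fluxes
(fatty-acid-, NADH-, succinate-linked) to the all-substrate internal
reference of the same run: $FCR_x = J_x / J_{ref}$.

## 3. Adenylate energetics and viability rules

Energy charge $(ATP + \tfrac12 ADP)/(ATP+ADP+AMP)$ and ATP:ADP are plain
ratios; both are scale invariant so units need only be consistent within a
panel. All-zero panels and zero ADP raise errors rather than returning
NaN.

The transplantability rules are conjunctive: lactate ≤ 2.5 mmol L⁻¹ at
some sample within the first 2 h (the criterion itself names no deadline;
the 2 h operationalization follows the clinical summary table and is
configurable), pH within 7.30–7.45 with fewer than two bicarbonate
additions ("repeated" read as ≥ 2; configurable), and AST, ALT, LDH each
≤ 20,000 U L⁻¹. IL-6 has no published threshold and is surfaced only as a
warning field, never gated.

## 4. AUC biomarkers and the outcome model

Each biomarker trajectory is integrated by the trapezoidal rule over a
window, default **0–6 h of NMP** with the cold-storage biopsy assigned
$t=0$: the clinical claim ties prediction to early NMP, and the biopsy
schedule provides observations at 0, 1 and (band-level) ~6 h. Observations
are clipped to the window by interpolation at the edges; the integral
never extrapolates beyond the first or last observation, and fewer than
two observations in the window gives a missing value that is excluded
(and counted) downstream. The AUC is raw value·hours by default; a
time-averaged variant is a flag.

**Selection.** Bidirectional stepwise AIC from the intercept-only model,
AIC $= n\log(RSS/n) + 2k$: at each step the single add/drop move with the
lowest AIC is taken, stopping when no move improves. Marginality is
enforced (an interaction may enter only while both parents are in; a
parent may not leave first), and AIC ties break lexicographically, making
the path deterministic. This is the standard greedy stepwise (it matches
`stats::step` exactly on shared scopes, verified in the tests). Being
greedy, it is a *local* optimizer: in regimes where an interaction carries
signal but its parents' main effects are individually undetectable, the
hierarchy rule can strand the search before the interaction becomes
admissible, and the result can differ from exhaustive enumeration over all
hierarchical submodels. The oracle-equivalence tests therefore run in
regimes with detectable parent effects (or main-effects-only scopes),
where greedy and exhaustive selection genuinely coincide.

**Inference.** OLS with per-term Type II sums of squares: each term's SS
is the RSS increase from deleting it from the largest submodel containing
no interaction that involves it; F uses the full model's residual mean
square. On orthogonal designs this reduces to sequential SS; the per-term
SS need not sum to the model SS (documented behavior, not a bug).
Standardized betas are $b\,\mathrm{sd}(x)/\mathrm{sd}(y)$; the published
model table contains b/beta sign inconsistencies that cannot be
reconciled from the printed values alone, so betas here are simply this
definition.
Partial residuals are component-plus-residual values
$r + b_j x_j$, whose regression on $x_j$ returns exactly $b_j$.

With 4 terms and $n = 20$ complete cases the overall F has (4, 15)
degrees of freedom and satisfies the closed form
$F = (r^2/4)/((1-r^2)/15)$ — with $r^2 = 0.40$ this gives 2.5, matching
the published model's footer up to coefficient rounding. Which 20 of the
35 transplanted livers entered that model is unstated in the source;
the package's missing-data policy is complete-case with a logged count.

## 5. The synthetic cohort: a stated world

No clinical data are deposited, so the generator *is* the test bed. What
it emulates, and what it does not:

* **Per-liver parameters.** Fluxes are lognormal — positive and
  right-skewed, matching the printed medians with scale solved from the
  printed IQRs ($\sigma_{\log} = (\log q_{75} - \log q_{25})/(2 \cdot
  0.674)$): S-pathway OXPHOS at median 40.23 (IQR 33.57–52.15), F at
  12.54, N at 4.81 pmol s⁻¹ mg⁻¹. Efficiencies are beta with means 0.8
  (P-L), 0.06 (cytochrome *c*), 0.40 (E-P) and concentration 50 — chosen
  so the P-L spread (sd ≈ 0.056) makes occasional livers dip toward the
  published extreme of ~0.55 without crossing zero.
* **Internal consistency.** Only $S_P$ and the efficiencies are drawn;
  LEAK, P꜀ and E are derived from them, so every record satisfies the
  coupling identities by construction.
* **Dynamics.** Between biopsies, parameters follow a random walk on the
  log/logit scale (drift sd 0.05 per step) plus observation noise (0.02).
  The published work reports *stability* of succinate-linked respiration
  during NMP but no between-time-point correlation; the random-walk drift
  is this package's construct, and nothing downstream depends on its
  exact form.
* **Outcome link.** The score is linear in AUC(P-L eff), AUC(cyt-c eff),
  AUC(LEAK) and the cyt-c × LEAK product — computed by the *same*
  `time_auc()` the analyzer uses, preventing definitional drift. Signs
  follow the published model (−, +, −, −). Magnitudes are not published
  in usable units (the printed coefficients applied to real AUC scales
  would produce scores orders of magnitude beyond the published score
  range), so they were fixed once by a power rule: each term contributes
  roughly 0.5–2 outcome SD given the flux scales above
  (−6, +5, −0.1, −0.05; intercept 32.2 centres the score near the
  published median of −0.83; residual sd 2 matches the published score's
  IQR width). Consequence: the three AUC main effects are recoverable by
  stepwise selection at $n=200$, while the raw-product interaction is
  heavily collinear with its parents and is selected in only ~40% of
  runs — reported in the tests, not gated.
* **Not emulated.** Histology, imaging, immune markers; any
  pharmacokinetic perfusate model beyond monotone trends (perfusate
  profiles are the published transplanted-group medians with lognormal
  liver- and sample-level scatter); reoxygenation events in long
  oxygraph runs; inter-analyte correlation in perfusate chemistry.

A green test against this world establishes that the *pipeline* is
correct and unbiased under stated noise — not that the clinical effect
sizes are right, which no test can establish without the undeposited
data.

**Seeds.** One root seed; per-liver child seeds derive deterministically
(`child_seed()`), so any single liver regenerates without the rest of the
cohort, and identical seeds give bit-identical output everywhere.

## 6. Numerical choices and degenerate inputs

* Trace integration is exact (closed-form exponential-blend integral) when
  the background is concentration-independent; with $b \ne 0$ an
  exponential-integrator step per sample is used (midpoint-frozen flux).
* Oxygen exhaustion before the protocol ends raises an error naming the
  step; the simulator does not model chamber reoxygenation.
* Traces must have strictly increasing time; events must be sorted and
  uniquely named; duplicate-chamber merges require matching step sets and
  propagate the worse QC flag; discordant duplicates (|a−b|/mean > 15%)
  are flagged, not dropped.
* `detect_plateau` ties break toward the earliest qualifying window;
  combined with the lexicographic stepwise tie-break, the entire pipeline
  is deterministic given data.
* Zero-variance predictors, singular designs, and residual df < 1 are
  errors, not warnings.

## 7. Known limitations

* The plateau CV gate is uninterpretable at high recording noise (§1);
  callers must adapt the config, and the defaults target low-noise
  clinical traces.
* Greedy stepwise is a local optimizer (§4); with hierarchically trapped
  signals it can under-select relative to exhaustive enumeration.
* The 0–6 h AUC window and the complete-case policy are choices the
  source leaves ambiguous (window stated in the abstract-level claim but
  not the model table; n=20 implied by the residual df). Both are flags.
* MEAF and EAD are carried as alternative outcome columns only; their
  internal scoring formulas are published elsewhere and are out of scope.
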