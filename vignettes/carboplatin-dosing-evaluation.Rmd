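---
title: "Evaluating carboplatin dosing algorithms by simulation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating carboplatin dosing algorithms by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbopk)
```

# The problem

Carboplatin is cleared almost entirely by glomerular filtration, and both
its efficacy and its haematological toxicity track systemic exposure, the
area under the concentration–time curve (AUC, mg·min/mL). Dosing therefore
targets an AUC directly through the Calvert relation
`dose = target AUC × (GFR + 25)`, with 25 mL/min representing non-renal
clearance. In routine care the GFR term is an estimated creatinine
clearance (CrCL), classically Cockcroft–Gault:

$$\mathrm{CrCL} = \frac{(140 - \mathrm{age}) \times \mathrm{weight} \times F_{sex}}{S_{cr}},$$

with serum creatinine in µmol/L and sex factors 1.23 (male) / 1.04
(female). Because creatinine production reflects muscle mass rather than
total body weight, Cockcroft–Gault with actual body weight overestimates
renal function in overweight patients and in cachectic patients with low
serum creatinine. The adjusted algorithm (`adjusted_cg()`) counters this
with three guard rails: adjusted ideal body weight when BMI ≥ 25 kg/m², a
serum-creatinine floor of 60 µmol/L, and a CrCL cap of 125 mL/min.

The package's purpose is to make the performance of this algorithm — and of
nine comparator estimators — measurable in simulation: how far does the
exposure a method would produce deviate from the target, per BMI stratum,
when the "measured" exposure comes from sparse-sampling pharmacokinetics?

# The estimator registry

`renal_methods()` enumerates the ten methods of the comparison grid. Each
returns a uniform `renal_estimate` whose `crcl` slot is the quantity that
enters the Calvert formula. Two families exist:

* **CrCL-type** methods estimate creatinine clearance (or eGFR): the
  adjusted and conventional Cockcroft–Gault variants, the measured 24-hour
  creatinine clearance, and both 2021 race-free CKD-EPI equations.
* **Direct-clearance** methods predict carboplatin clearance itself: the
  Chatelut-type model with the Bénézet ideal-weight substitution, the
  cystatin-C power model, and flat dosing. These store
  `clearance − 25` in the `crcl` slot so that the downstream Calvert
  reconstruction `crcl + 25` returns the formula's clearance exactly, and
  carry a `direct_clearance` flag so the offset is never added twice.

All numeric constants live in `formula_coefficients()`, overridable from a
YAML file (one named table per formula; an unknown or incomplete table is a
loud error). The defaults are transcribed from the original publications of
each equation. Unit notes: Cockcroft–Gault is implemented in its µmol/L
dialect; CKD-EPI converts serum creatinine to mg/dL internally (÷ 88.4) and
is de-indexed from mL/min/1.73 m² to absolute mL/min with Du Bois body
surface area by default — absolute units are required for dimensional
consistency in the Calvert formula; the toggle exists because practice
varies. The choice of Du Bois (rather than Mosteller) for BSA is itself a
design decision; it only affects the CKD-EPI de-indexing.

Ideal body weight is Devine (50 kg male / 45.5 kg female + 2.3 kg per inch
above 152.4 cm), extrapolated linearly below 152.4 cm; AIBW adds back 40%
of the excess over ideal. The boundary BMI of exactly 25.0 uses AIBW (the
lower edge of each BMI band is inclusive throughout).

Missing covariates (cystatin C for the cystatin-based methods, the urine
collection for the 24-h clearance) raise a typed condition and exclude the
patient from that method only — never silent imputation, mirroring
per-method exclusion in practice.

# Dosing

`calvert_dose()` is exact arithmetic; `round_dose()` maps the calculated
dose to the nearest multiple of the rounding increment. The default
increment is 50 mg — consistent with vial-based practice and with the one
worked example the source material prints (a calculated 620 mg administered
as 600 mg) — and exact midpoints round *down*, the toxicity-conservative
tie-break. Both are configurable; no dose cap is applied. The
rounding-induced AUC perturbation is bounded by `increment / (2·(CrCL+25))`
per patient, a bound the test suite propagates through the pipeline.

# The synthetic cohort generator

No patient-level data are published, so the generator emulates the study
conditions:

* **Stratum sizes 7/5/6** (<25.0, 25.0–29.9, ≥30.0 kg/m²), the evaluable
  cohort; dropout is not modelled.
* **Covariates uniform within each stratum's printed ranges** (age, weight,
  height, serum creatinine, cystatin C), resampled until the implied BMI
  lies inside the stratum band. Uniform sampling is the simplest model
  consistent with the printed medians-and-ranges information; the ranges
  are configuration, not code.
* **Sex probabilities from the printed per-stratum counts** (6/7, 1/5, 3/6
  male).
* **Target AUC from {5, 6} with P(6) = 0.8**, matching printed medians of
  6 with ranges 5–6.
* **Latent truth.** A designated truth formula (default: the adjusted
  algorithm itself) defines the reference clearance; the true carboplatin
  clearance is `(CrCL_truth + 25) · exp(η)` with `η ~ N(0, ω²)`, ω = 0.2
  (≈20% CV) by default — a typical carboplatin between-subject variability;
  the value is configuration since none is printed. The 24-hour urinary
  creatinine is back-computed from the latent creatinine clearance
  (`excretion = CrCL × S_cr × 1440/1000` µmol/24 h) with 10% multiplicative
  noise, so the measured 24-h clearance inverts the latent truth up to that
  noise — exactly, when the noise is switched off.

Choosing aCG as the default truth formula makes aCG unbiased by
construction, which is what makes the self-consistency tests sharp; setting
`truth_method = "CG_AIBW"` (or any other method) reproduces the qualitative
bias directions between weight descriptors in an obese stratum — ABW-based
dosing overshoots a truth that scales with lean mass — without claiming to
reproduce any study's quantitative values.

Per-patient random substreams are derived from the root seed and the
patient's global index, so enlarging one stratum never reshuffles
previously generated patients, and a fixed spec yields a byte-identical
cohort CSV.

What the generator does **not** emulate: covariate correlations beyond the
BMI-band constraint (weight–height dependence within a stratum, age–renal
function correlation), non-uniform covariate shapes, longitudinal cycles,
and assay failure/dropout. Passing tests therefore demonstrate the
arithmetic and estimation machinery under controlled conditions, not
real-data performance of any algorithm.

# The pharmacokinetic model

Ultrafilterable carboplatin follows a two-compartment model with zero-order
infusion input, in canonical units mg, mL, min. With micro-constants
`k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2`, the central concentration is the
standard biexponential convolved with the infusion; the implementation
superposes the infusion-start response with a negated copy shifted to the
infusion end, which makes continuity at the end of infusion structural
rather than numerical. The `(1−e^{−kt})/k` kernel is computed with
`expm1` (stable for small rates, and defined as `t` at rate zero, which
covers the one-compartment limit `Q → 0` without special-casing); a
repeated-root parameterisation (α = β) is handled by an epsilon split of
the double eigenvalue far below solver tolerance. Agreement with an
independent stiff-ODE integration (deSolve, lsoda) is ~1e-10 relative.

Population defaults: CL = 112.4 mL/min (the printed mean population
clearance); V1 = 20 L, Q = 0.5 L/min, V2 = 20 L are plausible-shape
placeholders, declared configuration — users wanting fidelity to a specific
published two-compartment carboplatin model should set them from that
source. Infusion duration defaults to 30 min (unstated in the source
material; configuration). Total exposure is `AUC∞ = dose/CL` exactly,
independent of V1, Q, V2.

The sampling design is the study's: pre-dose, end of infusion, and 1, 2.5
and 5 h after the end of the infusion. Residual error is proportional
(10% default) plus optional additive; the first-cycle pre-dose sample has
true concentration zero, is simulated as such, and is excluded from
fitting.

# MAP estimation

Individual clearance is estimated by maximising the standard empirical-Bayes
posterior, i.e. minimising

$$\sum_j \left[ \frac{(y_j - f_j)^2}{g_j^2} + \ln g_j^2 \right] + \eta^\top \Omega^{-1} \eta,
\qquad g_j^2 = \sigma_{prop}^2 f_j^2 + \sigma_{add}^2,$$

with the residual variance evaluated at the *current* individual prediction
(the interaction form). Only η on clearance is estimated by default —
exposure depends on clearance alone — with η on V1 available through the
variance model. Optimisation is BFGS from a multi-start (0 and ± one prior
SD per component) followed by Newton polishing with finite-difference
derivatives: BFGS stops on relative objective change, which on these stiff
1-D problems can leave the gradient above the convergence criterion
(gradient ∞-norm < 1e-6); the Newton steps drive it to machine level. Ties
between starts break by lowest objective, then smallest ‖η‖. Non-converged
fits are flagged and excluded downstream with a logged reason, mirroring
per-protocol exclusion.

Two numerical properties worth knowing:

* Under the interaction residual model the `ln g²` term makes the
  objective favour slightly *lower* predictions, so even data lying exactly
  on the population curve yield a small non-zero mode (≈0.01 on the η scale
  at the default σ). This is a property of the objective, shared with the
  estimators it emulates, not an optimiser defect; with an additive-only
  residual model the mode is exactly zero. The test suite asserts both.
* MAP shrinks: with the default 10% residual SD, even noise-free rich data
  are pulled ~0.5% toward the population mean. The recovery tests therefore
  match the fitting σ to the data's actual noise level, and the shrinkage
  limits (Ω → 0 gives the population value; σ → 0 gives the truth) are
  tested explicitly.

A brute-force grid search over η ∈ [−1, 1] at step 1e-4 serves as the
independent oracle; optimiser and grid agree to better than 1e-3 in η on
the sparse design.

# Evaluation

Every patient is dosed by the adjusted algorithm (the study design); their
*actual AUC* is administered dose / measured clearance, where the measured
clearance is the MAP estimate (or the simulation truth, when isolating the
dosing arithmetic from estimation error). For comparator methods two
readings of "estimated AUC" exist and both are implemented:

* **counterfactual** (default): the method's own rounded Calvert dose
  divided by the measured clearance — the exposure that method *would have
  produced*;
* **predicted**: the administered dose divided by the method's Calvert
  clearance.

The counterfactual reading is the default because it is the one under which
weight-descriptor biases have the expected signs (an ABW-based dose
overshoots a lean-mass-scaled truth in obese patients, AIBW does not); the
predicted reading matches the printed single-patient worked example. The
source material describes both without resolving them, so the switch is
explicit (`auc_mode`).

Prediction errors are percentages against the per-patient target AUC;
`mpe_mape()` returns the mean and mean-absolute errors with 95% Student-t
confidence intervals (the CI method is unstated in the source material;
t-based symmetric intervals are the conventional choice at these n).
`evaluate_cohort()` always emits the full 10-method × 3-stratum grid, with
per-method exclusions counted and the 85%–115% acceptance band flagged per
cell. MAPE ≥ |MPE| holds exactly by construction.

`required_sample_size()` is the normal-approximation calculation
`n = c·(z_{1−α/2}+z_{power})²·(sd/δ)²`; whether the original design was
one- or two-sample is unstated, and the two-sample reading is the one that
reproduces 7 per group for δ = 1.8 (30% of target AUC 6), SD 1.2, α 0.05,
power 0.80, so it is the default.

# Problem sizes and determinism

The shipped tests run the full pipeline at the study's own scale (18
patients) for self-consistency and directional checks, a 30-patient obese
stratum for the bias-direction check, 200 simulated patients for the
sparse-design MAP regression, and 1000 draws for distributional checks —
sizes at which every check completes in seconds while keeping Monte-Carlo
error well inside the asserted margins. All randomness flows from explicit
seeds; identical spec and seed give byte-identical cohort files, fits and
reports.

# Limitations

* The comparator formulas' coefficient sets are transcriptions of the
  cited original publications; laboratories with calibrated local variants
  should supply them through the YAML registry.
* The PK distribution parameters (V1, Q, V2) and variance magnitudes are
  declared placeholders; conclusions about *estimation* accuracy transfer
  only to the extent these resemble the drug's true kinetics.
* The generator's independence assumptions (uniform covariates, no
  weight–height correlation beyond the BMI band) make the synthetic strata
  somewhat wider than real clinic populations.
* Population-parameter estimation (FOCE/SAEM) is out of scope: the MAP
  step conditions on fixed population values, which is all the evaluation
  requires.
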