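---
title: "Modelling progress curves of the reconstituted kallikrein-kinin cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling progress curves of the reconstituted kallikrein-kinin cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kkscascade)
```

## The system and the model family

The minimal in vitro kallikrein–kinin system (KKS) mixes three purified
proteins: activated Factor XII (FXIIa), prekallikrein (PK) and native
high-molecular-weight kininogen (nHK). FXIIa activates PK into plasma
kallikrein (PKa); PKa cleaves nHK into cHK, the bradykinin-releasing
step. The assay runs on ice at a high enzyme/substrate ratio, and the
observable is the *cleavage fraction* of PK and nHK at nominal sampling
times between 30 s and 30 min — a progress-curve design, not an
initial-velocity design.

The core model is a pair of coupled Michaelis–Menten (MM) rate laws
(`cascade_rates()`), with FXIIa catalytic (never consumed by reaction
1) so that PK + PKa and nHK + cHK are conserved along any trajectory.
Default kinetic constants are the 0 °C estimates for this system:
kcat1 = 0.0119 s⁻¹, KM1 = 115 nM (FXIIa/PK) and kcat2 = 0.133 s⁻¹,
KM2 = 672 nM (PKa/nHK).

Measured progress curves deviate from the plain MM simulation in two
reproducible ways, and the model family (`kks_model()`, presets in
`kks_model_preset()`) covers the mechanisms considered for each:

* **Faster start.** (i) A presteady-state *initial burst*:
  `apply_initial_burst()` moves `inib·[F12a]₀` of PK into PKa and
  `inib2` times that amount of nHK into cHK at t = 0. (ii) A *stopping
  delay* Δt: pipetting into SDS buffer does not stop the reaction
  instantly, so a sample nominally taken at time t reflects reaction
  time t + Δt. The retained model fixes `inib2` at its maximal value 1
  (one nHK cleaved at once per burst-formed PKa) and Δt = 44 s.
* **Slower end.** (i) Product inhibition by cHK: competitive against
  reaction 1 (apparent KM1 multiplied by α₁ = 1 + [cHK]/KI1) and
  uncompetitive against reaction 2 (kcat2 and KM2 both divided by α₂).
  (ii) Alternatively, a zero-order FXIIa decay (`decay_rate`, nM/s,
  floored at [F12a] = 0); a rate of `0.75·[F12a]₀/1800` — leaving
  25 % of FXIIa activity after 30 min — is the benchmark magnitude
  for weighing this variant against the inhibition mechanism.

### The competitive-inhibition algebra

One typeset form of the reaction-1 rate law in circulation for this
cascade *divides* KM1 by (1 + [cHK]/KI1). That algebra accelerates
the reaction as cHK accumulates and therefore contradicts both the
"competitive" label and the slower late rate the model exists to
explain. We treat it as a typesetting slip: the default `competitive`
mechanism uses the textbook form KM1·(1 + [cHK]/KI1), and the
division variant remains available as mechanism `as_printed` so both
algebraic readings can be compared. Only the textbook form can
produce a late-phase slow-down.

### Burst bookkeeping

The burst equations specify what PKa and cHK jump *to* at t = 0 but
not whether the PK and nHK pools are decremented. We decrement both:
otherwise the conservation invariants break and cleavage fractions can
exceed 1. With this choice the burst appears as instantaneous cleavage
at t = 0 when fractions are computed against pre-burst totals — which
is how the data are presented, and why the model can reproduce the
apparent positive intercept of the progress curves.

### Offset orientation

"Experimental time = theoretical time + Δt" is ambiguous about which
clock runs ahead. We map nominal time t to reaction time t + Δt,
because the delay is physically a *late stop*: the reaction keeps
running for Δt after sampling. `predict_at_times(offset_sign = -1)`
provides the opposite orientation for sensitivity checks.

## Simulation

`kks_simulate()` integrates with deSolve's `lsoda` (adaptive,
stiff-capable) on a uniform grid of 36000 steps over 30 min (0.05 s
spacing) with rtol 1e-8 / atol 1e-10; the right-hand side is compiled
C, with `cascade_rates()` as the reference R implementation (`engine =
"R"` integrates through it and matches bit-for-bit in tests to 1e-10).
Conservation sums drift by less than 1e-6 relative over the full
window (observed: ~1e-14), and a fixed-step classical RK4 integrator
on the same grid — an independent oracle maintained in the test suite
— agrees to better than 1e-6 relative. Between grid points predicted
fractions are interpolated linearly; at 0.05 s spacing the induced
error is orders of magnitude below quantification noise. Linear
interpolation (rather than nearest-grid-point lookup) is our choice.

For fitting, trajectories are not needed on the display grid:
`kks_ssd()` asks `lsoda` for output exactly at the reaction times the
observations need, and stacks all assays of a collection into one
solver call (blocks of five species sharing one parameter set). On a
grid that contains the requested time, interpolation is the identity,
so this is purely a speed path — it changes no predicted value beyond
solver tolerance, and a test pins the batched SSD to the per-assay
simulate-then-predict route.

## Fitting and the stopping rule

The SSD objective is the plain sum of squared differences between
predicted and observed cleavage fractions over both species, all
samples, all assays — on the fraction scale (0–1), with PK and nHK
weighted equally (no weighting is documented; equal weights are the
natural reading). Time-0 samples are taken *before* mixing, so they
are excluded by default; `include_premix = TRUE` pins them against the
post-burst state at reaction time 0 instead.

The optimiser (`kks_fit()`) is deterministic cyclic coordinate
descent. Each cycle runs one line search per free parameter: a
multiplicative bracket expands from the current value (steps doubling
in the improving direction, clamped to bounds) and golden-section
search refines inside the bracket — in log space for KI1, KI2, Δt,
decay and the kinetic constants (positive scale parameters), linear
space for the burst coefficients. Warm-started fits (bootstrap
replicates) therefore search only a small neighbourhood. Default intervals: inib ∈ [0, 1], inib2 ∈ [0, 2],
KI ∈ [1, 1000] nM, Δt ∈ [0.5, 600] s. The line-search tolerance
(5e-4 of the interval) resolves parameters about a decade finer than
the stopping rule needs. Iteration stops when every free parameter,
rounded to two significant digits, repeats between consecutive cycles
— the two-first-digits stopping convention. The search strategy was
chosen because all free parameters are positive scalars and the
stopping rule is per-parameter. No random restarts: the SSD surface
over these one-to-three-parameter families is smooth and, in all
tested configurations, unimodal along coordinate slices.

`kks_compare()` ranks the named variants (`mm`, `burst`, `delay`,
`burst_delay`, `chki_inib`, `burst_decay`) by optimised SSD — raw SSD
only, deliberately without an information criterion. `kks_bootstrap()`
resamples whole assays with replacement (drawing n among n with
replacement is the resampling under which a dispersion arises at all),
refits each replicate from the full-data fit (warm start — replicates
then converge in a few cycles, keeping hundreds of replicates at desk
scale), and summarises with linear-interpolation quantiles (median,
2.5/97.5 %); the quantile convention is our choice.

## Single-enzyme estimation and QC

`gel_velocity()` implements the western-blot processing rules: the
first-minute velocity is (nHK₀ − mean T1)/60 s/[PKa] with the
*theoretical* initial nHK as substrate; the second-minute velocity
uses mean T1 as both substrate and starting concentration. Records are
rejected when the densitometry standard is not linear (Pearson R² ≥
0.98, configurable, after optionally dropping the single most helpful
point), when the T1 duplicates disagree by more than 20 % of their
mean (the tolerance is stated; the denominator is our reading), or
when T0/T1/T2 show abnormal or no cleavage progression.
`plate_velocity()` implements the chromogenic assay: A405 readings ≥
0.6 discarded (≈10 % substrate consumption), blank and CTI-control
correction, linear PKa standard curve (rejecting non-monotone or
sub-R²-floor standards), then PKa amount regressed on incubation time
with the intercept reported, not forced through the origin — a nonzero
intercept is itself evidence of the burst/stop-delay phenomenon.

`hanes_woolf_fit()` regresses S/v on S (slope 1/Vmax, intercept
KM/Vmax); `nonlinear_mm_fit()` refines by unweighted least squares
(Levenberg–Marquardt) and never returns a worse residual than its
start. Velocities are normalised per nM enzyme throughout, so Vmax on
that scale is kcat. A saturated data set drives KM to the zero
boundary; the fit is returned with a `boundary` flag rather than an
error.

## What the synthetic data emulate — and what they do not

`generate_progress_assays()` reproduces the canonical assay
conditions: ratio triples of a 30 nM unit (defaults 1/6/6, 1/6/3,
0.5/1/12; arbitrary triples accepted, since real campaigns span many
more concentration sets than the three canonical ones), sampling
between 30 s and 30 min (default grid 30, 60, 120, 240, 480, 900,
1800 s), 32 assays per collection, and mean-corrected multiplicative
lognormal noise on fractions. The noise cv defaults to 5 %:
densitometry has no canonical noise model, but the 20 %
duplicate-disagreement QC tolerance bounds a plausible cv well above
5 %, and western-blot quantification scatter of a few percent after
QC is typical. Gel records integrate
true single-enzyme MM decay exactly (implicit closed form solved by
`uniroot`), so the per-minute-average velocity definition carries the
same small finite-difference bias as the real assay. Synthetic plates
form PKa at rate × incubation time — the initial-velocity regime the
short-contact design aims for — with exact depletion integration
available via `deplete = TRUE`.

What passing tests on these data show is that the *pipeline* is
correct and well-conditioned: parameters that generated the data are
recovered (burst coefficient to ±0.05, inhibition constants to ±30 %
at 5 % noise over 32 assays), model ranking identifies the generating
mechanism, bootstrap intervals cover the truth. They cannot show that
the mechanistic interpretation of real curves is unique — competing
inhibition mechanisms can yield similar SSD on progress curves of
this information content, so the mechanism label should not be
over-interpreted from SSD alone.

## Numerical choices and problem sizes

Tolerances: solver rtol 1e-8/atol 1e-10; conservation asserted at
1e-6; line search 5e-4 of the search interval; optimiser cycle cap 200
(a cap hit raises a condition carrying the best iterate). Degenerate
inputs are rejected up front: negative concentrations, non-positive
KM/KI, bursts exceeding the available substrate pool, fewer than two
distinct substrate concentrations in a linearisation. Ties in variant
ranking keep input order.

The test suite exercises the statistical claims at desk scale, chosen
once as realistic smaller analogues of the full design: parameter
recovery uses 10 collections of 32 assays; bootstrap coverage uses 20
repeat experiments of 32 assays with 100 replicates each (the package
default of 600 replicates, the scale of a full dispersion analysis,
runs in about a minute per collection). The acceptance script reports
medians over 10 collections of 32 assays and a 100-replicate
bootstrap.

## Known limitations

The FXII→FXIIa positive feedback loop, serpin (C1-INH) control, the
PKa–nHK complex-transition and three-step acyl-enzyme models are out
of scope (their rate equations are not available in the source
material); the model family here is the printed one plus its variant
flags. SSD-based ranking has no penalty for parameter count — the
presets keep one to three free parameters precisely so that model
complexity stays far below the information content of the curves. Real densitometry noise is likely heavier-tailed
than lognormal; QC rejection rates under the generator should not be
read as calibrated estimates of real-world rejection rates.
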