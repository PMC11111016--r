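---
title: "Rapid stable-isotope labeling kinetics of auxin biosynthesis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rapid stable-isotope labeling kinetics of auxin biosynthesis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silkr)
```

## The measurement problem

Steady-state concentrations of a hormone say little about the fluxes that
maintain them. For indole-3-acetic acid (IAA), the principal bioactive
auxin, turnover half-times span minutes to hours, and the biosynthetic
intermediates (anthranilate, indole, tryptophan, indole-3-pyruvate) cycle
faster still. Resolving which step of the network an effector acts on
therefore requires watching isotopic label flow *through* the network on a
seconds-to-minutes time base: feed a heavy-labeled precursor, sample a time
series, and quantify, per compound, the isotopologue channels that separate
newly synthesized material from pre-existing pools and from the spiked
internal standard.

`silkr` implements the computational side of such an experiment: channel
design (exact masses, narrow extraction windows), narrow-window
quantification from centroided LC-MS runs, isotope-dilution concentration
estimates, incorporation-curve fitting, and a simulator that generates
complete synthetic experiments with known ground truth so that every stage
of the pipeline can be validated without instrument data.

## Channel chemistry

Each monitored channel is an isotopologue of a target ion. For IAA the
diagnostic ion is the quinolinium fragment cation C9H8N+ produced by
fragmentation of protonated IAA; ring substituents survive fragmentation,
so ring labels map directly onto fragment channels. Ion m/z is the sum of
the lightest-isotope atomic masses, plus a proton where the ion is
protonated, minus one electron mass per positive charge. The electron
correction (0.00054858 Da) matters at the 4th decimal: without it the
computed windows do not match the windows used in practice.

```{r}
q <- ion_mz("C9H8N")
mz_window(q)                          # unlabeled quinolinium
mz_window(labeled_mz(q, "13C6"))      # ring-13C6 tracer channel
mz_window(labeled_mz(q, "2H4"))       # ring-d4 internal standard
```

Heavy-isotope substitutions shift the base m/z by `count *
(heavy - light)` exact mass differences: +1.00335 per 13C, +1.00628 per
2H, +0.99703 per 15N. The shifts are additive across schemes, and high
resolution instruments separate them comfortably at narrow window widths.

Extraction windows default to an absolute half-width of 0.0010 m/z
(reported round-half-even at 4 decimals), which is narrow enough that the
natural 13C1 satellite of the unlabeled ion (at +1.00335) falls outside the
15N1 window (at +0.99703) — so no cross-channel natural-abundance
correction is applied by default. A ppm window mode and a cross-talk flag
on the target table exist for wider setups.

Natural-abundance isotopologue envelopes are computed by per-element
multinomial expansion: each element contributes a single-atom distribution
over nominal mass shifts, convolved across atoms and elements, aggregated
by shift and normalized to the monoisotopic peak. For IAA (C10H9NO2) the
M+1 abundance computed over all of C, H, N and O is about 11.4% of M+0;
counting only the dominant 13C and 15N terms gives about 11.2%, which is
why slightly lower figures are often quoted. The implementation always
reports the full-molecule value, validated in the tests against a
brute-force enumeration over every isotope assignment for small molecules.

```{r}
isotopologue_envelope("C10H9NO2", 2)
```

## Quantification

A channel's extracted ion chromatogram (EIC) is the per-scan sum of
centroid intensities inside the closed m/z window. Two ratio estimators are
provided:

* **Peak area**: trapezoidal integration between the target's configured RT
  bounds (optionally after subtracting the linear chord between the
  boundary intensities, clipping negatives at zero). Area mode mirrors
  manual peak selection in vendor software.
* **Regression slope**: ordinary least squares of the trace channel's
  intensity on the denominator channel's intensity across scans, with an
  intercept. On proportional channels the slope equals the area ratio
  exactly; under constant additive background the intercept absorbs the
  offset and the slope stays exact while the raw area ratio is biased by
  `background x window width` in both numerator and denominator. That
  robustness is the reason regression mode is preferred for low-abundance,
  high-background channels. The intercept is included by default; a
  zero-intercept and a weighted variant are available.

Concentrations come from isotope dilution: `conc = ratio x q_IS /
fresh_weight`, reported in ng per g fresh weight with fresh weight supplied
in mg. The canonical spiking scheme (10 ng of heavy IAA standard per mL of
homogenization buffer at 20 µL per 10 mg tissue, i.e. 0.2 ng per 10 mg)
makes a ratio of exactly 1 correspond to 20 ng/g. In reverse isotope
dilution an *unlabeled* standard is spiked, and the endogenous
(heavy-nitrogen) and tracer-derived channels are quantified concurrently
against the same denominator.

## Kinetic models

Label incorporation time courses are fitted by Levenberg–Marquardt least
squares (relative tolerance 1e-8, at most 10,000 function evaluations) to
one of three families:

* `first_order`: `y(t) = ymax (1 - exp(-k t))`, `k >= 0`, the step-labeling
  solution for a single well-mixed pool; the turnover half-time `ln 2 / k`
  is attached. Initialization: `ymax` from the data maximum, `k` from a
  log-linear regression of `log(1 - y/ymax)` on `t`.
* `sigmoid3`: `y(t) = a / (1 + exp(-(t - t0)/b))` for lagged
  incorporation; `b < 0` is permitted so monotone-decreasing series fit
  with the same family.
* `logistic4`: `y(t) = d + (a - d)/(1 + (t/c)^b)` with `c > 0`, the
  four-parameter logistic used by standard dynamic-regression curve
  fitters; initialized from quantiles of the response range.

When no model is named, every family admissible for the number of distinct
timepoints (3, 4 and 5 respectively) is fitted and the lowest-AICc fit is
returned — a pragmatic stand-in for proprietary "dynamic regression" model
pickers. Constant series, all-zero series and non-convergent fits come back
flagged rather than as spurious parameter values.

Treatment arms are compared per timepoint with a two-sided two-sample
Student's t test assuming equal variances (Welch behind a flag), with no
multiplicity correction by default (Holm available). This matches the
per-timepoint significance convention used with small biological replicate
sets (n = 3–5); the calibration of the test at n = 3 is itself checked in
the acceptance suite (type-I error 0.05 ± 0.01 over 10,000 simulated null
datasets).

## The simulator

The simulator is the package's ground-truth generator, not a fixture. A
`pool_network` holds metabolic pools (size in ng/g, chromatographic RT and
peak width, channel label schemes) and directed edges carrying first-order
rate constants applied to the upstream pool; the flux through an edge is
`rate x multiplier x upstream pool size` and a pool's turnover rate is its
total inflow divided by its size. Pools are at metabolic steady state; only
label fractions evolve. Under step labeling of the entry pool the label
fractions follow a constant-coefficient linear system, solved by matrix
exponential and cross-checked in the tests against a stiff ODE integrator;
an optional finite first-order uptake rate replaces the instantaneous step
where tracer uptake itself is limiting.

**Inhibitors.** An inhibitor scales selected edge rates by a multiplier in
[0, 1]. Two regimes are distinct and both are supported:

* *Pre-incubated* (default): the inhibitor has acted for many
  pool-turnover times before the tracer is applied — the usual protocol,
  with inhibitor plates prepared 20–30 h ahead. Downstream steady-state
  pool sizes are re-equilibrated to the reduced flux (each pool rescaled by
  the ratio of new to old inflow, resolved in topological order). Because
  pool sizes and fluxes scale together, label-fraction kinetics are
  unchanged while every downstream *concentration* channel scales with the
  multiplier — which is what makes treated and mock arms separable at every
  timepoint, late plateau included.
* *Acute* (`preincubated = FALSE`): the inhibitor arrives with the tracer.
  Pool sizes stay fixed and the label-fraction kinetics themselves slow
  down, giving strictly lower downstream label fractions at all finite
  times but converging plateaus.

One subtlety found while testing: with *parallel* inflow paths of different
label freshness, acutely inhibiting the staler path can transiently *raise*
a downstream label fraction, because the fresher inflow then dominates the
mixing balance. Monotonicity of label fractions in the edge multipliers is
therefore a theorem only for single-path cascades, and the property test
asserts it there.

**Rendering.** Each sample is rendered as a centroided run: per pool and
channel, a Gaussian elution profile at the pool's RT whose area is
`concentration x response factor`, plus the channel's natural-abundance
M+1 satellite computed from the atoms left at natural abundance after
labeling. Noise: one multiplicative log-normal draw per channel per run on
the amplitude (mean-preserving), optional additive baseline counts on every
scan, optional Poisson counting noise, and per-centroid ppm mass jitter.
All randomness derives from the mandatory config seed plus a deterministic
per-sample offset, so identical seeds give byte-identical runs.

**Default network.** The shipped configuration
(`inst/extdata/iaa_network.yaml`) is the anthranilate → indole → Trp →
IPyA → IAA cascade with a steady-state flux of 1 ng g⁻¹ min⁻¹: small,
rapidly cycling precursor pools (turnover 5, 4 and 8 min⁻¹ for indole, the
active Trp pool and IPyA — half-times of 5–10 s, consistent with the
premise that intermediates cycle on a seconds scale) feeding a 20 ng/g IAA
pool with turnover 0.05 min⁻¹ (half-time ≈ 14 min, inside the
minutes-to-hours range reported for IAA). These defaults are illustrative
of a realistic experiment, not calibrated to any particular dataset. The
fast-precursor regime also keeps the summed upstream residence time
(≈ 0.6 min) small against the IAA time constant, so a first-order fit to
the terminal pool estimates its turnover with only a few percent of
systematic lag bias; with slow upstream pools the terminal curve is
sigmoidal and the first-order `k` would underestimate turnover — the lag
families above exist for exactly that case. A Trp-independent indole → IAA
shunt edge can be toggled on for scenario studies.

**What the simulator does not emulate.** Retention-time drift between
runs, peak tailing, matrix-dependent ionization suppression, detector
saturation, isotope effects on rates, enzyme saturation
(Michaelis–Menten), and compartmentation are all absent. Passing the
simulator round trips therefore validates the arithmetic of the pipeline —
extraction, ratio estimation, dilution scaling, curve fitting — not its
robustness to those instrumental artifacts on real data.

## Numerical choices and problem sizes

* Window bounds are reported round-half-even at 4 decimals; this convention
  reproduces the standard printed windows exactly.
* EIC windows are closed intervals; boundary ties are included.
* Peak integration requires at least 3 points; regression at least 3
  points and a non-zero denominator channel; negative fitted ratios are
  floored at 0 in the pipeline table.
* The matrix exponential is evaluated per timepoint (networks here have
  ≤ 6 pools, so cost is negligible); fractions are clamped to [0, 1]
  against 1e-9-level overshoot.
* Validation studies run at desk scale by choice: the kinetic recovery
  study uses 200 simulated experiments (9 timepoints from 0.5 to 256 min,
  3 replicates, 5% amplitude noise) sampled at the quantification level —
  the ODE truth under the same log-normal amplitude noise the renderer
  applies — while full spectral rendering is exercised by the round-trip
  and background-bias checks; a test asserts the two paths agree noise-free
  to within quadrature error. The t-test calibration uses 10,000 null
  datasets at n = 3 per arm.

## Known limitations

* Only singly charged cations, protonated or charged-as-given; no adduct
  chemistry, no fine-structure (mass-resolved within a nominal shift)
  envelopes. Derivatized targets are handled by configuring the
  derivative's ion formula directly.
* Which precursor labels survive into a fragment ion is declared per target
  in configuration; the package does not compute atom mappings.
* No RT alignment, automatic peak detection, or smoothing: targets carry
  configured RT windows, and an apex ± k·FWHM auto-bound mode exists mainly
  for simulated data.
* The quantification model assumes the internal standard co-elutes with
  its analyte and shares its response factor — the standard isotope
  dilution assumptions.
* `run_kinetics` treats replicates as independent observations per
  timepoint; no mixed-effects structure, no Bayesian fitting, no
  network-wide flux estimation from the fitted channels.
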