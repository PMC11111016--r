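# silkr

Stable isotope labeled kinetics (SILK) analysis of auxin biosynthesis by
high-resolution LC-MS, in R.

## The problem

Indole-3-acetic acid (IAA), the principal bioactive auxin, is maintained by
a network of interconnected biosynthetic and catabolic fluxes that
steady-state concentration measurements cannot resolve. The SILK approach
feeds seedlings a heavy-labeled precursor (e.g. ring-¹³C₆ anthranilate or
¹³C₈,¹⁵N₁ indole), samples a rapid time series (30 s to ~4 h), and
quantifies — per pathway compound — the mass channels that separate newly
synthesized material from pre-existing pools: plants grown on ¹⁵N media
carry a heavy-nitrogen "endogenous" channel, tracer-derived material
appears at the tracer-shifted channel, and a spiked internal standard
provides the denominator for isotope-dilution quantification. For IAA the
channels are monitored on its diagnostic quinolinium fragment cation
(C₉H₈N⁺, m/z 130.0651), whose ring retains the precursor labels.

`silkr` implements the computational pipeline for such experiments, for
analysts running rapid-labeling studies who need their channel design,
extraction, quantification and kinetics in one reproducible toolchain:

* **Channel chemistry** — exact ion m/z with proton and electron-mass
  corrections, heavy-isotope shifts (Δ¹³C = 1.00335, Δ²H = 1.00628,
  Δ¹⁵N = 0.99703 Da), ±0.0010 m/z extraction windows, natural-abundance
  isotopologue envelopes by per-element multinomial expansion, and
  target-table/inclusion-list export.
* **MS data** — mzML/mzXML reading and mzML writing (via Bioconductor
  `mzR`), SIM-segment and PRM-precursor scan filtering.
* **Quantification** — narrow-window EICs; peak-area and regression-slope
  isotopologue ratios (the slope of trace vs. monoisotopomer intensity
  across scans, with an intercept that absorbs constant background);
  forward and reverse isotope dilution in ng per g fresh weight.
* **Kinetics** — first-order `y∞(1 − e^(−kt))`, 3-parameter sigmoid and
  4-parameter logistic fits (Levenberg–Marquardt, AICc model selection),
  turnover half-times `ln 2 / k`, and per-timepoint Student's t
  comparisons between treatment arms.
* **Simulator** — tracer kinetics through a metabolic pool network
  (linear ODE system, matrix-exponential solution) rendered as centroided
  LC-MS runs with ground truth, so the entire pipeline is testable without
  instrument data.

## Worked example

Design the IAA tracer channel, then simulate a mock vs. inhibitor
experiment and fit the incorporation kinetics:

```r
library(silkr)

q <- ion_mz("C9H8N")                 # quinolinium cation, 130.0651
mz_window(labeled_mz(q, "13C6"))     # ring-13C6 tracer channel
#> m/z window [136.0843, 136.0863]

round(isotopologue_envelope("C10H9NO2", 2), 4)  # IAA envelope
#>      M+0      M+1      M+2
#> 100.0000  11.3608   0.9972

net <- iaa_network()                 # anthranilate -> ... -> IAA cascade
cfg <- sim_config(seed = 42, noise_cv = 0.05)
qt <- simulate_quant_table(net, cfg,
        treatments = list(mock = NULL, inhibitor = c("Trp->IPyA" = 0.1)))

iaa  <- qt[qt$compound == "IAA" & qt$channel == "tracer", ]
mock <- iaa[iaa$treatment == "mock", ]
fit_first_order(mock$timepoint, mock$conc_ng_g)
#> <silk_fit: first_order>
#>   ymax = 19.6574, k = 0.0484932
#>   half-time t1/2 = 14.29 min
#>   RSS 8.291 on 27 points
```

The fitted plateau (19.7 ng/g) and rate (k = 0.048 min⁻¹, half-time
14.3 min) recover the generating network's 20 ng/g IAA pool and
0.05 min⁻¹ turnover from 27 noisy observations. Comparing arms per
timepoint shows the inhibited step (tryptophan aminotransferase edge at
10% activity) suppressing tracer-channel IAA at every sampling time:

```r
inh <- iaa[iaa$treatment == "inhibitor", ]
compare_timepoints(mock$timepoint, mock$conc_ng_g,
                   inh$timepoint, inh$conc_ng_g)[, c("time", "mean_a", "mean_b", "p")]
#>    time  mean_a  mean_b        p
#> 1   0.5  0.0924 0.00913 6.95e-06
#> 2   1.0  0.4564 0.04562 6.55e-08
#> ...
#> 9 256.0 19.5532 1.90033 4.75e-07
```

`mean_a`/`mean_b` are the mock/inhibitor replicate means (ng/g); `p` is
the per-timepoint two-sample Student's t p-value (n = 3 per arm, no
multiplicity correction).

For on-disk workflows, `generate_experiment()` writes mzML runs plus truth
and manifest CSVs, `run_quantify()` processes a manifest against a target
table, and a thin CLI (`inst/cli/silk.R`) exposes `targets`, `simulate`,
`extract`, `quantify`, `kinetics` and `report` subcommands over the same
functions.

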