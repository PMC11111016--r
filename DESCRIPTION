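Package: silkr
Title: Stable Isotope Labeled Kinetics for Auxin Metabolism by LC-MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Targeted isotopologue analysis of rapid stable-isotope labeling
    experiments on the indole-3-acetic acid (IAA) biosynthetic network.
    Computes exact ion masses, narrow extraction windows and natural-abundance
    isotopologue envelopes for multi-tracer label schemes; reads and writes
    centroided LC-MS runs (mzML/mzXML); extracts narrow-window ion
    chromatograms and integrates chromatographic peaks; quantifies labeled and
    unlabeled channels by regression-slope or peak-area isotope dilution; fits
    first-order, three-parameter sigmoid and four-parameter logistic
    label-incorporation kinetics with per-timepoint group comparisons; and
    ships a synthetic-experiment simulator (tracer kinetics through a
    metabolic pool network rendered as LC-MS runs with ground truth) so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    mzR,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
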