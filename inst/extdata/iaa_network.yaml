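# Default synthetic IAA biosynthesis network.
#
# Pools are rapidly cycling biosynthetic pools at metabolic steady state:
# sizes in ng per g fresh weight, retention times and chromatographic peak
# widths in minutes. Edge rates are first-order constants (1/min) applied to
# the upstream pool, giving a steady-state flux of 1 ng/g/min along the main
# chain; intermediate pools turn over in seconds, IAA with a half-time of
# about 14 min. Channel label schemes: endogenous material is heavy-nitrogen
# labeled (grown on 15N media; Trp carries two nitrogens), the tracer is
# ring-13C6 from labeled anthranilate, and internal standards are unlabeled
# compounds except for IAA, which uses the ring-d4 standard and is monitored
# via its quinolinium fragment cation (C9H8N+).
pools:
  - name: anthranilate
    ion_formula: C7H7NO2
    protonated: true
    pool_size: 2.0
    rt: 3.4
    peak_sd: 0.05
    baseline_label: 15N1
    tracer_label: 13C6
    is_label: ""
  - name: indole
    ion_formula: C8H7N
    protonated: true
    pool_size: 0.2
    rt: 5.8
    peak_sd: 0.05
    baseline_label: 15N1
    tracer_label: 13C6
    is_label: ""
  - name: Trp
    ion_formula: C11H12N2O2
    protonated: true
    pool_size: 0.25
    rt: 1.8
    peak_sd: 0.05
    baseline_label: 15N2
    tracer_label: 13C6
    is_label: ""
  - name: IPyA
    ion_formula: C11H9NO3
    protonated: true
    pool_size: 0.125
    rt: 4.6
    peak_sd: 0.05
    baseline_label: 15N1
    tracer_label: 13C6
    is_label: ""
  - name: IAA
    ion_formula: C9H8N
    protonated: false
    pool_size: 20.0
    rt: 5.2
    peak_sd: 0.05
    baseline_label: 15N1
    tracer_label: 13C6
    is_label: 2H4
edges:
  - from: anthranilate
    to: indole
    rate: 0.5
  - from: indole
    to: Trp
    rate: 5.0
  - from: Trp
    to: IPyA
    rate: 4.0
  - from: IPyA
    to: IAA
    rate: 8.0
# Trp-independent shunt, off by default (iaa_network(shunt = TRUE))
shunt_edges:
  - from: indole
    to: IAA
    rate: 0.05
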