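# Monitored-channel configuration for the IAA pathway analysis: the
# quinolinium fragment cation of IAA (C9H8N+) with the heavy-nitrogen
# endogenous channel, ring-13C6 tracer channel and ring-d4 internal
# standard, plus the protonated molecular ions of the upstream intermediates
# quantified by reverse isotope dilution against unlabeled standards.
design:
  baseline: 15N1
  tracer: 13C6
  internal_standard: 2H4
  half_width: 0.0010
compounds:
  - name: IAA
    ion_formula: C9H8N
    protonated: false
    rt_min: 4.9
    rt_max: 5.5
  - name: Trp
    ion_formula: C11H12N2O2
    protonated: true
    rt_min: 1.5
    rt_max: 2.1
    segment: "200-217"
    baseline_label: 15N2
    tracer_label: 13C6
    is_label: ""
  - name: anthranilate
    ion_formula: C7H7NO2
    protonated: true
    rt_min: 3.1
    rt_max: 3.7
    segment: "133-150"
    is_label: ""
  - name: indole
    ion_formula: C8H7N
    protonated: true
    rt_min: 5.5
    rt_max: 6.1
    is_label: ""
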