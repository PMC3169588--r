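# Example config for `fungiqpcr-cli.R simulate` / run_simulate().
# community: annotated collection with planted FR1/FF390 sites.
# plate: qPCR standards + unknowns from a known standard curve.
community:
  set_name: FR1_FF390
  forward: {name: FF390, sequence: CGATAACGAACGAGACCT}
  reverse: {name: FR1, sequence: AICCATTCAATCGGTAIT}
  k_guard: 3
  groups:
    - {label: Ascomycota, n_sequences: 40, length: 600, is_fungal: true,
       fwd_prop: 0.9, rev_prop: 0.9, product_length: 368}
    - {label: Basidiomycota, n_sequences: 40, length: 600, is_fungal: true,
       fwd_prop: 0.5, rev_prop: 0.5, product_length: 368}
    - {label: Metazoa, n_sequences: 40, length: 600, is_fungal: false,
       fwd_prop: 0.0, rev_prop: 0.0}
plate:
  slope: -3.3219
  intercept: 38.0
  standards: [300, 3000, 30000, 300000, 3000000, 30000000]
  noise_sd: 0.15
  n_replicates: 3
  n_ntc: 3
  unknowns:
    - {sample: soil_A, copies: 25000, template_ng: 2.5}
    - {sample: soil_B, copies: 250000, template_ng: 2.5}
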