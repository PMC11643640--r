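# Regime scan over TRPC5 x GIRK conductance under saturating NKB + dynorphin
# drive, OVX parameter state: grid CSV + firing/silent boundary JSON.
stages:
  - stage: scan
    state: OVX
    x_param: g_TRPC5
    y_param: g_GIRK
    n: 5
    protocol: nkb_dyn_synch
    seed: 7
    dt_out: 0.5
    init_ms: 3000
    classes_a: [silent]
    classes_b: [tonic, irregular, irregular_burst, phasic_burst]
    output: regime_grid.csv
    boundary_output: boundary.json
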