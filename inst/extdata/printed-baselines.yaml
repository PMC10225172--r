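# Exact-arithmetic analysis on the published landmark risks: no data, no
# randomness, reproduces the excess-risk and NNH grids.
mode: printed-baselines
endpoints: [pcsm, crpc, metastasis]
multipliers: [1.25, 1.5, 1.75, 2.0]
baselines:
  pcsm:       {5: 0.0014, 10: 0.0099, 15: 0.0217}
  crpc:       {5: 0.0020, 10: 0.0250, 15: 0.0335}
  metastasis: {5: 0.0070, 10: 0.0290, 15: 0.0347}
precision: 2
seed: 1
out_dir: results/printed
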