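# End-to-end run: generate a synthetic 920-man cohort calibrated to the
# published landmark survival, fit Kaplan-Meier per endpoint, read landmark
# risks off the curves and build the scenario grids.
mode: full-pipeline
endpoints: [pcsm, crpc, metastasis]
multipliers: [1.25, 1.5, 1.75, 2.0]
horizons: [5, 10, 15]
cohort:
  n_subjects: 920
  endpoint_hazards:
    pcsm:       {landmark_survival: {5: 0.999, 10: 0.990, 15: 0.978}}
    crpc:       {landmark_survival: {5: 0.998, 10: 0.975, 15: 0.966}}
    metastasis: {landmark_survival: {5: 0.993, 10: 0.971, 15: 0.965}}
  accrual_years: {first: 1988, modal: 2011, last: 2017}
  study_end_year: 2017
  dropout_rate: 0.01
  seed: 20230409
precision: 2
seed: 20230409
out_dir: results/pipeline
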