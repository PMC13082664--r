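{
  "simulation": {
    "n_subjects": 6,
    "trials_per_subject": 2,
    "trial_duration": 30,
    "fs": 200,
    "cycle_mean": 1.1,
    "cycle_cv": 0.03,
    "stance_fraction": 0.6,
    "contralateral_offset": 0.5,
    "noise_sigma": 0.3,
    "seed": 20260909
  },
  "labeling": {
    "threshold": 0.5,
    "min_gap": 0.05,
    "reference_side": "right"
  },
  "dataset": {
    "fs_out": 100,
    "w": 20,
    "offset": 1,
    "n_test_subjects": 2,
    "split_seed": 11,
    "balance_seed": 12
  },
  "model": {
    "choice": "cnn",
    "config": {}
  },
  "training": {
    "epochs": 3,
    "seed": 13
  },
  "output_dir": "gaitphase_run"
}
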