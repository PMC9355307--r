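seed: 11
outdir: circsca_toy_out
simulate:
  n_per_group: 3
  n_circ: 100
thresholds:
  min_circCPM: 25
  min_samples: 5
contrasts:
  - case: 45X
    control: 46XX
  - case: 47XXY
    control: 46XY
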