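# Balanced desk-scale fragment-count dataset (synthetic).
n_samples: 120
n_relevant: 4
copies_per_relevant: 1
n_irrelevant: 16
flip_noise: 0.1
label_noise: 0.05
minority_fraction: 0.5
count_mode: binary
seed: 20260101
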