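# Imbalanced desk-scale dataset (synthetic): 10% minority, the strongest
# imbalance at which n = 200 still leaves enough positives to stratify
# 5-fold CV.
n_samples: 200
n_relevant: 4
copies_per_relevant: 1
n_irrelevant: 16
flip_noise: 0.1
label_noise: 0.02
minority_fraction: 0.1
count_mode: binary
seed: 20260102
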