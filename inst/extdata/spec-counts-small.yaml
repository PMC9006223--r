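# Poisson-counts desk-scale dataset (synthetic): presences carry small
# positive integer fragment counts.
n_samples: 120
n_relevant: 4
copies_per_relevant: 1
n_irrelevant: 16
flip_noise: 0.1
label_noise: 0.05
minority_fraction: 0.4
count_mode: poisson-counts
seed: 20260103
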