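# Small synthetic experiment: 6 constant + 8 fluctuating populations,
# full 75-cell cross-transfer design, 2 replicates.
constant_salinities: [0.8, 2.4, 3.2]
constant_replicates: 2
fluct_rhos: [-0.5, 0, 0.5, 0.9]
fluct_counts: [2, 2, 2, 2]
series_length: 80
replicates: 2
t_days: 3
n0_mean: 3911
n0_sd: 283
nb_size: 20
bb_precision: 10
seed: 1
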