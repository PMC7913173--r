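# One cell of the Monte-Carlo recovery study, at harness scale.
# Keys map to bws_scenario() / bws_control() arguments.
n: 250
theta: 1.0
residual_sd: 0.5
weights: [0.1, 0.3, 0.2, 0.1, 0.3]
correlation: low-moderate
n_replicates: 150
base_seed: 101
iterations: 6000
burn_in: 1000
thin: 2
chains: 1
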