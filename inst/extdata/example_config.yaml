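# Example simulation configuration: keys mirror sim_params() arguments.
# Unlisted parameters keep their package defaults.
U3: 3
kappa00: 10
n_steps: 100000
record_every: 5000
seed: 1
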