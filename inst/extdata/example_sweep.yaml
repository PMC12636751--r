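# Example sweep specification for the `sweep` CLI command.
# u3_values are required; kappa00_values makes it a full phase diagram.
u3_values: [1, 3, 10, 17.3, 30]
n_replicates: 10
seed0: 1000
threshold: 2
base:
  kappa00: 10
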