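# example pipeline configuration
n_permutations=2000
rng_seed=42
dual_congruent_scope=across
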