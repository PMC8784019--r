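# Example experiment plan: the full study grid at reduced replication.
n_obs: [30, 60, 120]
n_levels: [3, 5, 10]
n_reps: 2000
seed: 1
beta0: 73
beta1: 2
beta2: 0.2
sigma2_site: 1
sigma2_resid: 1
var_x: 0.5
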