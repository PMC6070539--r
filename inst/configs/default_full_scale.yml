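# Full-scale baseline: 3x3 gradient landscape, 100,000 generations,
# 9 environmental optima. One replicate of this configuration is a single
# long simulation; the full-scale experiment runs 50 replicates per
# parameter set (use the `sweep` CLI subcommand or sweep_factor()).
n: 3
landscape: gradient
delta_x: 1.0
random_width: 4.0
f: 1.0e-3
c: 5.0e-5
cr: 0.0
borders_closed: false
r: 1.0
K_star: 150
sigma_K: 1.0
sigma_C: 0.4
m: 1.0
dispersal: island
L_x: 16
L_a: 16
mu_k: 1.0e-3
s_x: 0.1
s_a: 0.2
mu_n: 1.0e-3
init_sd: 0.1
c_am: 0.2
AMT: 0.01
GIT: 15
max_tries: 50
horizon: 100000
snap_interval: 100
init_per_site: 150
record_vitals: false
check_propensities: false
gap_threshold: 0.2
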