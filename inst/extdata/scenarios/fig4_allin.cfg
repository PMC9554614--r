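description = Anisotropy sweep baseline with all 80 receptors in the nanocolumn
nnt = 1000
n_c = 80
n_r = 0
ani = 0.5
D_ani = 100
R_std = 50
H_c = 20
duration_ms = 3
n_reps = 1000
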