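# Opening/capture statistics of identified receptors: the layout is held
# fixed across repetitions.
description = Receptor opening and molecule capture statistics, nnt = 20000
nnt = 20000
n_c = 40
n_r = 40
ani = 0.5
D_ani = 100
R_std = 50
H_c = 20
duration_ms = 3
n_reps = 50
fixed_layout = true
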