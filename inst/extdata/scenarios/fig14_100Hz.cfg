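# 100 Hz train with a nanocolumn: "grouped" receptor diffusion, nanocolumn
# receptors at 0.01 um^2/s confined inside, the rest at 0.1 um^2/s outside.
description = 100 Hz train of 5 releases with a nanocolumn, grouped receptor diffusion
nnt = 5000
n_c = 40
n_r = 40
ani = 0.5
D_ani = 100
R_std = 50
H_c = 20
D_r = 0.1
frequency_hz = 100
n_events = 5
n_reps = 20
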