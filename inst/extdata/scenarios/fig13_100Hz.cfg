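# 100 Hz release train, no nanocolumn: receptor lateral diffusion ("free"
# mode) mitigates cumulative desensitization.
description = 100 Hz train of 5 releases, 80 PSD receptors, receptor diffusion
nnt = 10000
n_c = 0
n_r = 80
ani = 0
D_ani = 100
R_std = 50
H_c = 20
D_r = 0.1
frequency_hz = 100
n_events = 5
n_reps = 20
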