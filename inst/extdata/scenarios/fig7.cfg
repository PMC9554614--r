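# Viscosity protocol: run once with D = 0.30 and once with D = 0.15 um^2/ms
# and compare peak currents.
description = Halved glutamate diffusion coefficient vs normal, n_c = 80, ani = 0
nnt = 5000
n_c = 80
n_r = 0
ani = 0
D = 0.3
D_ani = 100
R_std = 50
H_c = 20
duration_ms = 3
n_reps = 200
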