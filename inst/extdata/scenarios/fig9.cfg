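# Release-site offset baseline (release_offset varied externally, 0-300 nm).
description = Displaced release site, mixed receptor placement
nnt = 1000
n_c = 40
n_r = 40
ani = 0.5
D_ani = 100
R_std = 50
H_c = 20
release_offset = 0
duration_ms = 3
n_reps = 1000
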