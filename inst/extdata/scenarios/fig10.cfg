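# Random vesicle openings over the PSD: charge transfer during the first
# 2 ms, correlated with the distance to the synapse centre.
description = Random release sites on the PSD, charge-distance correlation
nnt = 1000
n_c = 40
n_r = 40
ani = 0.5
D_ani = 100
R_std = 50
H_c = 20
duration_ms = 2
n_reps = 1
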