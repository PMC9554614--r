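# Dense nanocolumn cluster under a saturating release: maximal cleft
# depolarization at the current peak.
description = Cleft depolarization with all 80 receptors in the nanocolumn
nnt = 20000
n_c = 80
n_r = 0
ani = 0.5
D_ani = 100
R_std = 50
H_c = 20
duration_ms = 1
n_reps = 20
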