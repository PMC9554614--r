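## Small shared fixtures: reduced-size parameter sets used across test files.

fig3_params <- function(nnt = 1000) {
  simulation_parameters(nnt = nnt, n_c = 40, n_r = 40, ani = 0.5,
                        D_ani = 100, R_std = 50, H_c = 20)
}

## a tiny cleft (few field cells, few receptors) for fast coupled runs
tiny_params <- function(nnt = 50, ...) {
  simulation_parameters(R = 200, H_c = 20, nnt = nnt, n_c = 5, n_r = 5,
                        D_dr = 200, D_ani = 100, ...)
}

fast_numerics <- function(duration_ms = 0.25, ...) {
  numerics_config(duration_ms = duration_ms, ...)
}

## model curve of the biexponential template (t in ms)
biexp_curve <- function(t, Q, tau_rise_ms, tau_decay_ms) {
  Q / (tau_decay_ms - tau_rise_ms) *
    (exp(-t / tau_decay_ms) - exp(-t / tau_rise_ms))
}
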