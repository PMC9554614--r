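# cleftsim

Particle-based Monte Carlo simulation of transmission at a glutamatergic
synapse organised by a **trans-synaptic nanocolumn** — a ~100 nm structure
that aligns the presynaptic vesicle release site with a dense cluster of
postsynaptic AMPA receptors and fills the cleft with filaments that hinder
lateral diffusion of the transmitter.

The package is for computational neuroscientists who want to ask how
sub-microscopic synaptic organisation — receptor placement, cleft height,
release-site alignment, transmitter count, receptor mobility — shapes the
amplitude and kinetics of the synaptic current, at a scale where continuum
concentration models stop being trustworthy (a single small vesicle's worth
of glutamate, ~16% of which is actually captured by receptors).

## The model in brief

* **Glutamate**: every molecule is tracked individually. Per time step
  (Δt = 50 ns) a molecule moves a distance √(6DΔt) ≈ 9.5 nm along a random
  direction (D = 0.3 μm²/ms); inside the nanocolumn zone (diameter `D_ani`)
  the lateral components are scaled by `1 − ani`. Membranes reflect;
  the cleft rim (r ≥ R) absorbs, standing in for astrocytic clearance.
* **Receptors**: two binding sites, nine states
  (C0–C2 closed, O2 open, D1/D2a–D2d desensitized), literature rate
  constants; binding converts a molecule within the 5 nm capture region
  into an equivalent concentration C_eq = 1/(N_A·⅔πb³) ≈ 6.3 mM, so
  p_bind = k_on·C_eq·Δt per step. `n_c` receptors cluster under the release
  site (radial law −R_std·ln(1−u)), `n_r` are uniform over the 400 nm PSD.
* **Cleft potential**: a finite-volume solve of current conservation,
  n·g_unit·(v−E_intra) = −Δ₅v·H_c/Res with v = 0 at the rim, re-solved
  whenever the open-channel configuration changes. The field reduces each
  channel's driving force (current/conductance decoupling) and drifts the
  charged transmitter along the lateral gradients.
* **Outputs**: ensemble-mean current I(t), peak current and conductance,
  total charge Q = ∫I dt, the biexponential fit
  Ĩ(t) = Q/(τ_decay−τ_rise)·(e^(−t/τ_decay) − e^(−t/τ_rise)),
  proportion of transmitter captured (PNC), per-receptor opening counts,
  desensitized fraction, maximal cleft depolarization.

See `vignettes/cleftsim-methods.Rmd` for assumptions, numerical choices and
limitations.

## A worked example

Simulate the canonical mixed synapse — 40 nanocolumn + 40 PSD receptors,
`ani = 0.5`, 20 nm cleft — for a small vesicle of 1,000 glutamate
molecules, 30 repetitions:

```r
library(cleftsim)
p <- simulation_parameters(nnt = 1000, n_c = 40, n_r = 40, ani = 0.5)
r <- run_ensemble(p, numerics_config(duration_ms = 3), n_reps = 30, seed = 1)
r
#> Simulation result: 30 repetition(s), nnt = 1000, 80 receptors, 3 ms at dt = 50 ns
#>   mean peak current 17.3 pA, mean charge 12.4 fC, max cleft depolarization 1.59 mV
unlist(summary_metrics(r)[c("peak_pA", "peak_g_pS", "Q_fC", "driving_force_mV", "pnc")])
#>          peak_pA        peak_g_pS             Q_fC driving_force_mV              pnc
#>         17.34850        270.83333         12.41885         64.05599          0.15960
fit_biexponential(r)
#> Biexponential fit: Q = 11.91 fC, tau_rise = 53.55 us, tau_decay = 0.5679 ms (mse 0.245, converged)
```

Reading the numbers: at the ensemble-mean peak ~11 of 80 channels are open
(271 pS / 25 pS); the cleft hyperpolarizes by up to 1.6 mV, so the
effective driving force at the peak (64.1 mV) sits slightly below the
nominal 65 mV; 16% of the released molecules bind at least once (PNC); the
current rises in ~54 μs and decays in ~0.57 ms carrying ~12 fC of charge. Doubling the vesicle
(`nnt`) raises the peak sub-linearly — receptor occupancy saturates — which
is exactly the regime where the nanocolumn matters most.

Ready-made protocol presets are listed by `list_scenarios()` and loaded by
`build_scenario("fig2A")` etc.; release trains with laterally diffusing
receptors run through `run_train()`.

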