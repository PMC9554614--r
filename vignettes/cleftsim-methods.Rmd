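---
title: "Modelling synaptic transmission at a nanocolumn synapse with cleftsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling synaptic transmission at a nanocolumn synapse with cleftsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cleftsim)
```

## The model

cleftsim simulates a single glutamatergic synapse at the level of individual
molecules and receptors. The synaptic cleft is a thin cylinder of radius
`R` = 1000 nm and height `H_c` (10-50 nm, default 20). At `t = 0` a vesicle
of radius `r_ves` = 20 nm opens at the presynaptic membrane and deposits
`nnt` glutamate molecules, area-uniformly over the vesicle footprint. (A
20 nm vesicle holds about `vesicle_content(20, 300)$n_molecules` ~ 6000
molecules at 300 mM, which motivates the 200-20,000 range for `nnt`.)

Three coupled processes are then advanced on a common time step:

1. **Glutamate diffusion.** Each free molecule takes a step of fixed length
   $\sqrt{6 D \Delta t}$ along a fresh direction drawn uniformly on the
   sphere, the discrete-time walk whose displacement statistics converge to
   Brownian motion with diffusion coefficient `D` = 0.3 um^2/ms
   (`msd_validation()` recovers `D` from the mean square displacement to
   within a percent). The presynaptic and postsynaptic membranes are
   reflective; the lateral rim of the cylinder is absorbing, standing in for
   clearance by perisynaptic astrocytes. A *trans-synaptic nanocolumn* is
   modelled as a disk of diameter `D_ani` at the cleft centre in which
   cleft-spanning filaments hinder lateral motion: inside it the xy
   components of the random step are scaled by `1 - ani`, with z motion
   unaffected. The helper `filling_from_factor()` connects `ani` to the
   volume fraction of filament obstacles that would produce the same
   effective hindrance (a factor-10 reduction corresponds to a filling
   fraction of about 0.78).

2. **Receptor kinetics.** AMPA receptors are points on the postsynaptic
   membrane with two binding sites and nine gating states: closed with 0, 1
   or 2 bound glutamates (C0, C1, C2), one open state (O2), and five
   desensitized states (D1 with one ligand, D2a-D2d with two). The rate
   constants follow published AMPA receptor gating schemes (Budisantoso et
   al., 2012, J. Neurosci.). Binding transitions (C0 to C1, C1 to C2, D1 to
   D2a) are bimolecular: a free molecule inside a receptor's capture region
   binds with probability $k_{on} C_{eq} \Delta t$ per step, where the
   equivalent concentration $C_{eq} = 1/(N_A \cdot \frac{2}{3}\pi b_{rad}^3)$
   (~6.3 mM for `b_rad` = 5 nm) is the molar concentration represented by
   one molecule in the capture half-sphere. All other transitions are first
   order with probability rate x dt. A bound molecule is frozen until its
   receptor releases it.

3. **The cleft electric field.** Open channels pass current into the thin
   cleft, depolarizing the membrane at the synapse centre and reducing the
   local driving force; because the cleft is only tens of nanometres high
   this effect is not negligible when many channels cluster under the
   vesicle. Neglecting capacitive currents, current conservation per
   finite-volume element (20 nm square base, full cleft height) balances the
   transmembrane current $n_{ij} g_{unit} (v_{ij} - E_{intra})$ against the
   lateral Ohmic currents $(v_{ij} - v_{neighbour}) H_c / \mathrm{Res}$,
   with `v = 0` on the rim. With the intracellular potential fixed at its
   resting value (-65 mV), open channels pull `v` negative; the membrane
   depolarization is `-v`. The solved field feeds back twice: the driving
   force of each open channel becomes `v - E_intra`, and the (-1 charged)
   glutamate molecules drift along the lateral potential gradients with
   mobility $D F / (R_g T)$.

Receptor placement mirrors the nanocolumn organisation: `n_c` receptors
cluster around the synapse centre with radial distances drawn as
$-R_{std} \ln(1 - u)$ (angle uniform), aligned with the release site, while
`n_r` receptors are area-uniform over the 400 nm PSD disk. Although this
radial law is often described loosely as a "Gaussian cluster", the formula
is an exponential radial profile, and `place_receptors()` implements the
formula verbatim; a hard-core exclusion of 10 nm between receptor centres
accounts for receptor size. Nanocolumn draws are only constrained to the
cleft radius, not to the PSD: the exponential tail occasionally places a
cluster receptor beyond 200 nm, which we accept rather than truncating the
stated law.

In release-train protocols (`run_train()`) receptors may additionally
diffuse laterally on a 10 nm exclusion lattice with move probability
$4 D_r \Delta t / h^2$ per step. A receptor stepping off the synapse is
replaced by a naive (C0) receptor at a random rim cell — the model's way of
exchanging desensitized receptors with the extrasynaptic pool — or, in
"grouped" mode, nanocolumn and PSD receptors are confined to their
respective regions with separate diffusion coefficients.

## Numerical choices

**Time step.** `dt` = 50 ns makes the per-step displacement
$\sqrt{6 D \Delta t} \approx 9.5$ nm, comparable to the physical extent of a
receptor, and keeps every transition probability below 3e-3 so the
first-order discretization of the Markov chain is accurate (the sampled
dynamics match the matrix exponential of the generator within Monte Carlo
error; see the test suite). The step length is always derived from
`sqrt(6 * D * dt)` — reducing `dt` reduces it accordingly.

**Capture geometry.** Receptors are not modelled as 3-D objects, so the
capture region is a convention. The default (`"cylinder"`) treats it as the
space the receptor protrusion occupies: xy distance to the receptor within
`b_rad` and height within `b_rad` of the postsynaptic membrane. The
alternative (`"hemisphere"`) uses the 3-D distance to the receptor's
membrane anchor point. The two differ by ~1.5x in eligible volume and hence
in capture flux; the cylinder convention is the default because it
reproduces the reference opening and capture statistics of this synapse
configuration (see README). $C_{eq}$ uses the half-sphere volume in both
cases, keeping the published formula.

**Order of sub-updates** within a step: field-gradient lookup (from the
last solve), position update, boundary conditions, capture, Markov
transitions, receptor lateral diffusion (train mode), field re-solve,
recording. At 50 ns any fixed order gives indistinguishable results; this
one follows the causal chain release -> diffusion -> binding -> gating ->
current. Anisotropy membership and the gradient cell are evaluated at the
molecule's pre-step position. At most one binding event per molecule and
per receptor per step; several eligible molecules compete for a receptor in
randomized order.

**Reflection.** A single reflection per face per step is applied
(`z -> |z|`, `z -> 2 H_c - z`); a position still outside afterwards aborts
with advice to reduce `dt`. At the default step length this can only occur
for `H_c` below ~9.5 nm.

**Field solve.** The linear system is solved only on steps where the
open-channel configuration changed; in between, the potential is constant.
The exported `solve_potential()` assembles the sparse symmetric system and
solves it directly. The engine exploits the structure of the update instead:
the operator is a fixed source-free five-point Laplacian plus a diagonal
term on the handful of elements holding open channels, so the solution is
obtained exactly by the Woodbury identity from cached columns of the
inverse Laplacian (each column computed once per element by
IC(0)-preconditioned conjugate gradients to a relative tolerance of 1e-12).
Both paths agree with a dense solve to 1e-8 (tested). An element belongs to
the disk iff its centre does; gradients use centred differences in the
interior and one-sided differences next to the grounded rim.

**Biexponential fit.** Summary kinetics come from fitting
$I(t) = \frac{Q}{\tau_d - \tau_r}(e^{-t/\tau_d} - e^{-t/\tau_r})$ to the
ensemble-mean current by Levenberg-Marquardt least squares. The two time
constants are interchangeable in the template, so the fit parameterizes
$\tau_d = \tau_r + e^{\theta}$, which enforces the ordering and removes the
symmetry; initial values use half the time-to-peak, a log-linear fit of the
tail and the trapezoidal charge, with four jittered restarts because the
objective is multimodal. Fits are meaningful for ensemble means, not for
single noisy repetitions.

**Repetitions and seeds.** Ensemble results average `round(1e6 / nnt)`
repetitions (clipped to 20-1000), balancing trace smoothness against cost;
train simulations use 20. Each repetition runs on an independent
xoshiro256++ substream derived from the root seed, so results are
bit-reproducible for a given seed and independent of scheduling. The engine
draws sphere directions by the polar (rejection) method, which has exactly
the same uniform-on-sphere law as the inverse-CDF construction used by the
exported `sample_unit_vectors()`.

## The receptor scheme's connectivity

The nine states and twenty-two rate constants are standard; how the four
deep desensitized states interconnect is not uniquely pinned down by
published rate tables, so the package fixes a topology subject to the
structural constraints that (i) exactly the three transitions quoted in
M^-1 s^-1 are bimolecular, (ii) O2 is the only conducting state, (iii) C0
is the unique absorbing state once glutamate is removed, and (iv) recovery
from desensitization is dominated by exits of order 25-400 s^-1 so that the
desensitized pool drains on the tens-of-milliseconds scale seen in paired
and train stimulation. The chosen connectivity is C2 <-> D2a, D2a <-> D2b,
C2 <-> D2b, C2 <-> D2c, O2 <-> D2d and D2c <-> D2d on top of the canonical
C0-C1-C2-O2 backbone and the D1 branch; `ampar_kinetic_scheme()` returns
the full edge table and `write_scheme()` serializes it for inspection.
Alternative assignments of the deep-state edges leave the fast transient
nearly unchanged but shift late-time desensitization; the choice above
reproduces the reference opening statistics and charge transfers across
vesicle sizes (README). Two known consequences: simultaneous open-channel
counts at saturating glutamate top out near 70% of the population, so peak
cleft depolarizations cluster around 4-4.6 mV for an 80-receptor
nanocolumn, somewhat below the largest values reported for comparable
configurations (~5.5 mV); and the deep-state/open exchange re-injects
openings late in the transient, putting the fitted decay constant of the
small-vesicle mean current near 0.55-0.65 ms, on the slow side of the
0.4-0.5 ms typical of fast AMPA responses.

## What the scenario catalogue does and does not emulate

The shipped scenarios (`list_scenarios()`) are parameter files, not data:
the model itself generates every input from physical constants, so passing
tests demonstrate internal consistency of the simulator and agreement with
the closed forms and reference statistics encoded in the test suite — not
agreement with any particular experimental recording. Real synapses differ
in ways the model deliberately omits: receptor geometry is a point with a
capture radius; the intracellular potential is clamped (no spine-neck
electrotonics); there is no NMDA component, no transporter kinetics beyond
the absorbing rim, a single nanocolumn at most, and quantal release is
instantaneous.

## Problem sizes

Default scenario sizes follow the `1e6/nnt` repetition rule. The test suite
and the acceptance script use reduced repetition counts (e.g. 50-100
repetitions at `nnt` = 1000, 10-20 at `nnt` = 20,000) and window lengths
that cover the transient being measured (3 ms for charge and opening
counts, ~1 ms for peak-only quantities); these sizes give Monte Carlo
standard errors comfortably inside the tolerances asserted. All remaining
discrepancies are stated in the README rather than absorbed into wider
tolerances.

## Known limitations

* The deep-desensitization connectivity is a reconstruction (see above);
  late-time (>10 ms) state occupancies should be treated as
  scheme-dependent.
* The capture region is a convention for a receptor that has no explicit
  geometry; absolute capture probabilities inherit that convention.
* The cleft potential is quasi-static between open-channel configuration
  changes and the intracellular side is an ideal voltage source.
* The anisotropy zone is a sharp-edged disk; real filament crowding is
  graded.
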