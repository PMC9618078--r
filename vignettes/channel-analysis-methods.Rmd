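---
title: "Methods: ion permeation, conductance, and membrane energetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ion permeation, conductance, and membrane energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreflux)
```

# Scope and conventions

poreflux is the analysis layer for channel simulations: it consumes
particle trajectories and produces functional observables. It does not
run molecular dynamics, solve 3D electrostatics, or fit force fields.
Units are global: lengths nm, times ns, energies kcal/mol (kT where
flagged), currents pA, potentials mV, conductances pS. The axial
coordinate increases from the intracellular to the extracellular side;
outer→inner traversals are reported with positive sign (the plotting
convention for cation influx), and this sign map lives in one place,
`channel_geometry()`.

# Permeation counting

The permeation pathway is a cylinder (default radius 1.2 nm) around the
channel axis, with a compartment-boundary plane at the hydrophobic gate
and end planes 7.5 nm toward the extracellular and 5.0 nm toward the
intracellular domain — the compartment bookkeeping convention of
double-bilayer computational electrophysiology.

Counting proceeds in two stages. `unwrap_axial_tracks()` converts wrapped
axial coordinates into continuous tracks using minimum-image
displacements, flagging any step of at least half a box length as a
teleport (a CompEL swap); flags reset the detector rather than being
unwrapped. `detect_permeation_events()` then runs a per-particle
three-state machine (outside / entered-from-outer / entered-from-inner):
an event is emitted only when a particle passes beyond the far end plane
after entering past the near one, with the radial criterion evaluated at
the boundary-plane crossing frame. Design choices worth making explicit:

* **Radial criterion at the boundary crossing only.** The cylinder defines
  the swap-exempt pathway, not a confinement tube, so a transient lateral
  excursion between the end planes does not cancel a traversal.
* **Conservative start-up.** A particle that begins inside the channel can
  complete at most a half traversal and emits nothing.
* **Debouncing.** Re-crossings of an end plane flip the state machine back
  and forth without emitting; an event requires the full
  near-plane → boundary → far-plane pattern. This is our explicit rule for
  flickery boundary behaviour.
* **Antiparallel copies.** In double-bilayer geometry the two channels are
  detected separately with outer→inner orientation defined per copy, then
  concatenated.

The detector is continuously validated against an exhaustive-scan oracle
(a pattern scan over the full per-particle crossing list, implemented
independently in the test suite) on randomized Langevin trajectories.

# Currents, conductance, selectivity

Currents are computed from event counts (transition counting), not from
instantaneous charge flux: `I = Σ direction·valence·e / window`, in 20-ns
windows with 10-ns overlap by default. At desk scale this estimator is
noise-free given the events.

`fit_iv_conductance()` fits `I = G·V + b` by ordinary least squares and
reports the slope in pS with a 95% Student-t interval. The intercept (a
reversal-potential offset) is reported but not folded into G; a
zero-intercept mode is available since either convention appears in the
literature. Subsets `depolarized` (V > 0) and `polarized` (V < 0) mirror
the common practice of fitting the two branches separately; the full-set
slope always lies between the branch slopes.

`applied_field_conductance()` implements `G = N·|z|·e/(t·|V|)` for
fixed-field runs, with a sign-consistency check of the net flux against
the driving potential. Equal event counts therefore give a divalent ion
exactly twice the conductance of a monovalent one — a pure unit
consistency property the tests pin down.

`selectivity_ratio()` reports the cation:anion event-count ratio with a
Wilson score interval on the cation fraction (well-behaved at small
counts and at zero anion events, where the ratio is reported as infinite
with a one-sided interval). The charge-current ratio (valence-weighted)
is reported alongside, since a 1:1 permeation ratio of a divalent versus
monovalent cation corresponds to a 2:1 current ratio.

# Transmembrane potential profiles

`potential_profile_from_charge()` double-integrates the 1D Poisson
equation from a charge-density profile in e/nm³. Charge neutrality is
enforced before integration. By default a linear ramp is subtracted so
the net potential difference across the box is zero and both ends sit at
0 mV, and the grid is recentered at the box midpoint — the convention
that minimizes asymmetric rounding in double integration. The unramped
solution is exposed (`force_zero = FALSE`) because closed-form
comparisons such as the parallel-plate capacitor are only exact there.
Relative permittivity defaults to 1, appropriate when all charges are
explicit.

# Free-energy profiles

`wham_pmf()` implements the standard self-consistent WHAM iteration over
bin probabilities and window free energies, converging when no window
free energy moves by more than a tolerance (default 1e-6 kT, cap 1e5
iterations). Bias constants are taken in kJ/mol/nm² (the MD engine's
unit) and converted internally. Numerical choices: the default bin width
is span/200; unsampled bins are masked NA, never ±Inf; adjacent windows
must share at least one occupied bin or a connectivity error names the
gap; a single unbiased window reduces algebraically (and in the tests,
exactly) to Boltzmann inversion. Profiles are referenced so the minimum
over the bulk region is zero; when no bulk region is supplied, the
flattest 10%-of-span stretch of the outer quarters is chosen — the
profile is zeroed at bulk solvent, but the exact convention is otherwise
arbitrary, so it is explicit and overridable.

`boltzmann_invert()` computes `−kT ln(ρ/ρ_bulk)` for unbiased densities,
and `profile_features()` extracts barriers and wells per labeled region,
reporting the global maximum as the primary barrier and wells sorted by
depth.

# Pore radius

`pore_radius_profile()` re-implements minimal pore-radius profiling in
the spirit of the HOLE/CHAP family: per axial slice, the radius is the
largest sphere centered in the slice plane touching no atom,
`max_(x,y) min_i (|p − x_i| − R_i)`, located by a deterministic
Nelder–Mead search (fixed start, tight tolerance, one restart at the
converged point to sharpen the conical optimum) seeded from the previous
slice's center. Reproducibility is preferred over speed. A search that
escapes the structure's bounding cylinder marks an open-pore slice,
capped at a configurable ceiling radius. Arbitrary pore axes are handled
by rigid rotation, and the profile is invariant under rigid motion of the
structure to 1e-6 nm.

# Membrane thickness and compression

`thickness_map()` grids headgroup markers in the membrane plane,
assigning leaflets by the instantaneous midplane, time-averaging per-cell
heights, optionally smoothing with a separable NA-aware Gaussian kernel,
and masking cells with too few markers (e.g. under the protein
footprint). This gridded-binning stand-in for surface triangulation is
validated against the synthetic generator's analytic ground truth.

`compression_penalty()` evaluates the quadratic leaflet-compression
penalty `G = (K_A/2) Σ (u/l)² S_cell` with `u = (thickness − t_bulk)/2`
(leaflets treated symmetrically) and `l = t_bulk/2`. The symmetric split
is the default because the penalty's definition provides no asymmetry
treatment; a per-leaflet mode computes the two deformations separately.
Masked cells are excluded from the sum, matching a grid average taken
only where lipids exist. `K_A` defaults to 60 kT/nm², a typical bilayer
area stretch modulus; results are reported in kT and kcal/mol at the
stated temperature, and on an analytic Gaussian deformation the grid sum
reproduces the closed form `(K_A/2)(u0/l)² πσ²` within 1%.

# Contacts, occupancy, residence

`contact_series_from_traj()` uses dual-cutoff hysteresis (bind at
0.475 nm, release beyond 0.7 nm), the coarse-grained convention of
occupancy/residence tools; these defaults are implementation choices, not
measured values, and a single-cutoff atomistic mode is obtained by
setting both cutoffs equal. Occupancy is any-ligand occupancy (a site is
bound if any ligand is in contact), which is the natural reading when
ligands are exchangeable; same-ligand continuity would give lower values
for fast-exchanging ligands. Residence times exclude censored boundary
intervals and estimate the unbinding rate by a least-squares exponential
fit to the empirical survival curve. Density maps are normalized per
frame so total mass equals the mean in-slab ligand count; the joint
pair-distance mode is flagged unstable when its bin holds under 5% of the
mass. Coordination numbers use strict `<` cutoffs (defaults Na⁺ 0.32,
K⁺ 0.36, Ca²⁺ 0.30 nm to oxygen — typical first minima of ion–oxygen
radial distribution functions, configurable).

# Synthetic generators and what they do (not) show

Every downstream stage is testable because the generators know their own
truth:

* `simulate_ion_channel()` integrates overdamped Langevin dynamics,
  `dz = −(D/kT) U'(z) dt + √(2D dt) ξ`, with
  `U = PMF(z) + z_i·e·φ(z)` and φ dropping the applied potential linearly
  across the channel span (approximating the membrane-focused field of
  applied-field MD). Defaults: dt = 0.01 ns, D = 1 nm²/ns (bulk-ion-like);
  a stability guard rejects steps whose deterministic energy change
  exceeds 2 kT. Lateral coordinates diffuse inside the pathway cylinder.
  With periodic axial boundaries the potential's seam discontinuity
  supplies the nonconservative loop work that sustains a steady-state
  flux, for which `smoluchowski_current()` gives the exact stationary
  quadrature solution — the analytic reference for the whole conductance
  pipeline.
* `apply_compel_swaps()` exchanges ion/placeholder position histories to
  hold a target compartment charge imbalance, flagging every teleport.
  Swaps are applied instantaneously; the multi-step smoothing of
  engine-internal implementations is not emulated.
* `generate_membrane_surfaces()` builds Gaussian leaflet deformation
  fields (`thickness = t_bulk − 2 u0 e^{−r²/2σ²}` plus noise) and
  `simulate_membrane_beads()` scatters headgroup markers on them.
* `simulate_binding_series()` is a two-state Markov chain with per-frame
  transition probabilities `1 − e^{−k dt}` and stationary occupancy
  `k_on/(k_on + k_off)`.
* `sample_umbrella_windows()` draws exact samples from each biased
  density by rejection from the bias Gaussian.

These generators emulate the statistical structure the analysis assumes
— 1D drift–diffusion, Markovian binding, Gaussian height fields. They do
not contain explicit water, 3D electrostatics, lateral ion pathways,
correlated multi-ion motion, or lipid dynamics. Passing tests therefore
demonstrate the correctness of the analysis layer, not the realism of any
particular simulation; applied to real trajectories the usual caveats of
sampling and force-field accuracy apply unchanged.

# Problem sizes and statistical tolerances

The test suite runs generator fixtures at sizes chosen to make its
statistical assertions sharp while staying quick on one CPU: conductance
recovery uses 50 ions for 300 ns at five voltages in the linear-response
range (0, ±25, ±50 mV), where ~10²–10³ events per run put the fitted
slope within a few percent of the stationary quadrature; detector–oracle
agreement uses 100 randomized 15-ns runs; WHAM recovery uses 15 windows
of 2000 samples over a 3 kT double well (barrier error below 0.2 kT);
occupancy/rate recovery uses 10⁴ ns of the two-state chain (k_off within
20%). Statistical assertions use 3σ bands derived from the generators'
own laws (binomial counts, Markov-chain autocorrelation time
`τ_c = 1/(k_on + k_off)`), never ad hoc margins. A 40 kcal/mol central
barrier — the resting-gate regime — is checked to block all traversals,
with the stationary quadrature confirming the expected event count is
vanishingly small (Kramers-limit behaviour) rather than merely unsampled.

# Known limitations

* Orthorhombic boxes and a z-aligned channel axis only; triclinic cells
  are rejected.
* Events are axial-pathway only; lateral-portal (intracellular
  fenestration) pathway classification is out of scope.
* The WHAM implementation has no built-in autocorrelation correction;
  windows are assumed to contain effectively independent samples (true
  for the rejection sampler, approximate for MD data).
* `density_map_2d()` and `pair_distance_hist2d()` expect one marker
  particle per ligand; center-of-mass reduction of multi-bead ligands is
  the caller's responsibility.
* Adaptive-bias (AWH) free-energy estimation is not implemented;
  externally computed profiles can be consumed as `pmf_profile` tables.
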