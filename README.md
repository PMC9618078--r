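# poreflux

Trajectory-analysis toolkit for ion-channel simulations: permeation-event
counting, single-channel conductance, free-energy (PMF) profiles, pore
radii, membrane compression energetics, and lipid/ligand contact
statistics — with built-in synthetic generators so every stage can be
validated against known ground truth without running a molecular dynamics
engine.

## Who this is for

Researchers analysing molecular dynamics simulations of membrane channels
— in particular pentameric ligand-gated ion channels (pLGICs) such as the
α7 nicotinic acetylcholine receptor — who need the downstream analysis
layer that turns raw particle trajectories into functional observables:
currents, conductances, selectivity, potentials of mean force, membrane
deformation penalties, and state-dependent lipid interaction maps.

## What it computes

**Permeation and conductance.** A full channel traversal is detected by a
per-particle state machine over a cylindrical pathway (radius 1.2 nm by
default) around a compartment-boundary plane, with end planes 7.5 nm
toward the extracellular and 5 nm toward the intracellular side. Counting
is robust to periodic wrapping and to the position swaps of
computational-electrophysiology (CompEL) double-bilayer setups. Events are
converted to windowed currents (20 ns windows, 10 ns overlap),
current–voltage datasets, and conductances:

- I–V slope: ordinary least squares `I = G·V + b` with a 95% CI on `G`
  (pS = pA/mV × 1000), on the full dataset or the depolarized/polarized
  subsets;
- applied-field formula: `G = N·|z|·e / (t·|V|)` for fixed-potential runs;
- selectivity: cation:anion event-count ratio with a Wilson interval.

**Potentials and free energies.** Transmembrane potential profiles by
double integration of a 1D charge density with a zero-net-difference
constraint; PMFs by the weighted histogram analysis method (WHAM) over
umbrella windows, or by Boltzmann inversion `−kT ln(ρ/ρ_bulk)` of unbiased
densities; barrier/well extraction from profiles.

**Membrane mechanics.** Leaflet height fields and thickness maps from
headgroup markers, radial thickness profiles, and the quadratic
compression penalty

    G_compression = (K_A / 2) Σ_grid (u/l)² S_grid

with `u` the per-leaflet deformation from the unperturbed leaflet
thickness `l` and `K_A ≈ 60 kT/nm²`, reported in kT and kcal/mol.

**Contacts.** Dual-cutoff (0.475/0.7 nm) hysteresis contact series,
per-residue percent occupancy, residence times with survival-curve
exponential fits, 2D ligand density maps in an axial slab, joint
pair-distance distributions, and strict first-shell coordination numbers.

**Synthetic generators.** Overdamped Langevin (drift–diffusion) ion tracks
through a 1D PMF with a linear applied-potential drop, CompEL-style swap
bookkeeping, Gaussian membrane deformation fields, two-state Markov
binding series, and exact rejection-sampled umbrella windows — each
recording its ground truth, plus a stationary Smoluchowski quadrature
(`smoluchowski_current()`) as an analytic conductance reference.

## Worked example

Drive 50 Na⁺ ions through a flat-PMF channel at +200 mV, count
traversals, and compare the event-counting conductance with the analytic
stationary-flux reference:

```r
library(poreflux)
spec <- channel_sim_spec(
  diffusion = c(Na = 1), valence = c(Na = 1L), n_ions = c(Na = 50L),
  voltage = 200, channel_span = c(3, 7), box = c(6, 6, 10),
  dt = 0.01, cyl_radius = 1.0, seed = 42)
traj <- simulate_ion_channel(spec, n_steps = 20000, save_every = 5)
geom <- channel_geometry(boundary_z = 5, cyl_radius = 1.2,
                         extent_out = 2.5, extent_in = 2.5,
                         center_xy = c(3, 3))
events <- detect_permeation_events(traj, geom)
tally_events(events, dt_grid = 1)
#> event_tally: 402 events over [0, 198.2] ns, net charge +400 e
#>   cumulative by species: Na +400
applied_field_conductance(events, V = 200, duration = 200)
#>   species n_events     G_pS sign_consistent
#> 1      Na      400 1602.177            TRUE
smoluchowski_current(spec)
#>    species flux_per_ns current_pA     G_pS
#> Na      Na    1.901983   304.7313 1523.657
```

400 net outer→inner traversals in 200 ns at 200 mV give 1602 pS by the
applied-field formula, within statistical noise (~5% at 400 counted
events) of the 1524 pS stationary drift–diffusion solution for the same
potential — the two estimates come from entirely different routes (event
counting vs quadrature), so their agreement validates the pipeline.

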