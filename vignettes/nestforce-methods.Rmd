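---
title: "nestforce: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nestforce: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: the equations it
integrates, the parameters that matter and why their defaults are what they
are, what the packaged scenarios emulate (and do not), and the decisions we
made where the design was genuinely open. Every empirical statement here is
recomputed by the test suite; nothing below reports a number the tests do
not themselves produce.

## 1. The model

### Particles

The universal entity is a hollow sphere: a particle has a position, a
velocity, a radius `r > 0`, a density `ρ > 0`, a species (which fixes an
attribute schema and physical defaults), an arbitrary attribute map, and a
parent link. Parent links form a forest; a particle's contents are the
particles whose parent it is. The same machinery represents a 2 nm protein,
a 50 nm vesicle, a lipid raft and a 4 µm cell. Mass is computed as a solid
sphere of the particle's density (no shell thickness is modelled); in 2D a
unit slab thickness (1 m) is the convention, so `m = ρ π r²`. Particles are
"deformable" only implicitly, through the elastic overlap of the contact
law — there is no deformation state beyond the overlap depth.

### Motion

Mobile particles follow the Langevin equation
`m ẍ = −γ ẋ + f(t) + F_ext(x, t)`. Friction is Stokes drag `γ = 6π η r`,
kept in 2D as well because no clean 2D Stokes analogue exists (the 2D MSD
target becomes `4 D t`). The viscosity `η` a particle feels is the
`interior_viscosity` of the innermost ancestor that declares one, else the
medium's — this is how a raft slows its guests by exactly 10×.

The thermal force is Gaussian per component with variance
`σ² = 2 γ k_B T / Δt`. The underlying description leaves this variance open;
we impose the fluctuation–dissipation value because it is the unique choice
for which the equilibrium velocity variance is `k_B T / m` per component and
the long-time MSD is `2 d D t` with the Stokes–Einstein
`D = k_B T / (6π η r)` — both properties the acceptance suite measures (3%
and 5% tolerances respectively).

### Forces

* **Excluded volume.** Hertz contact, `F = (4/3) E* sqrt(r_eff d³)`, with
  `E*` composed per species pair from Young's moduli and Poisson ratios and
  `r_eff` the reduced radius. Species defaults are `E = 10³ Pa`, `ν = 0.3`;
  `ν` must be below 0.5 (registration rejects 0.5 to avoid the
  incompressible-limit division blow-up). For sparse systems the exact
  elastic law is immaterial, so the exponent 1.5 is a model option
  (`stiffness_exponent`), any positive polynomial being acceptable.
  A contained particle overlapping its own shell from inside is pushed back
  toward the container centre; Newton's third law holds for every pair.
* **Reactive force.** A pair matching a bimolecular rule replaces Hertz
  contact with the constant repulsion `F = W / d*` while overlapping; the
  reaction triggers at overlap depth `d > d*`. The work to penetrate to the
  trigger is exactly `F · d* = W`, so `W` is the microscopic energy barrier;
  `W = 0` is the diffusion-limited case in which the pair passes freely.
* **Division force.** During fission each member of a half receives
  `F = m_i · a` along ± the division axis, so the halves move uniformly
  (equal acceleration, not equal force). The force profile is pluggable in
  principle; only the constant `m·a` profile is validated.
* **Global fields.** Arbitrary per-particle force functions, filtered by
  species and attributes. The packaged dipole-like field pulls a vesicle
  toward one of two poles selected by its coat attribute, abstracting
  motor-protein transport.

### Reactions

Zeroth- and first-order reactions are sampled every step. A first-order
rule fires with probability `1 − exp(−λΔt)` (never above 1, identical to
`λΔt` to first order); `λ` is an arbitrary function of the particle's
attributes and contents, which is how non-spatial chemistry — e.g.
`A(b, c) → A(d) @ b·c·k` — runs inside a spatial simulation. At most one
reaction per particle per step; simultaneous candidates are resolved by a
uniform random draw from the main RNG stream. **Deviation:** zeroth-order
rules draw their per-step event count from `Poisson(λΔt)` instead of a
single Bernoulli test. No particle identity constrains order 0, the
Bernoulli scheme biases the mean count by ≈ `−λΔt/2` per event, and the
Poisson draw is exact at any step size — the birth criterion (mean and
dispersion over 200 seeds) is then step-size independent.

Newly created particles enter at 1/100 of their target radius and grow
linearly over `growth_time`; sudden radius changes would create deep
overlaps, a large artificial potential energy, and numerical heating.
Shrinking has no such hazard, so explicit shrinks (`p_set_radius()`) are
immediate — the vesicle scenario uses this for exact volume bookkeeping
during budding (see §4).

**Division** replaces the parent by two children at the parent's position
and radius, assigns each content particle to a child (fair coin by default,
or a user split function), installs ignore relations (children mutually;
each content against the opposite child's shell), and pushes the halves
apart with the division force while the radii interpolate linearly in the
separation fraction `s = separation / (r_t1 + r_t2)`. At `s = 1` the halves
are exactly fully outside one another; ignore relations are removed and
normal propagation resumes. Contents are assigned at the start (the
ignore-relation setup requires knowing the membership). Compartment fusion
as reverse division is not implemented.

**Nesting/unnesting** use the same reactive force. Nesting triggers when
the entering particle is fully contained (`|x_i − x_j| + r_in ≤ r_shell`);
the phrase "fully passed over the outline" is geometrically ambiguous, and
full containment is the reading under which reparenting causes no jump in
any force term. Unnesting triggers at full exit
(`|x_i − x_j| ≥ r_in + r_shell`). For nesting rules the natural `d*` is the
full crossing distance `2 r_in` (the raft scenario uses exactly that), which
makes the total work against the constant force equal `W`. A nested
particle with no unnest rule meets ordinary inward contact force at the
shell and cannot leave. After a trigger the pair reverts to Hertz contact
immediately; whether the original design kept the reactive force on
already-reacted pairs is unknowable from the description, and reverting is
the choice that cannot double-fire.

## 2. Integration and time step

The integrator is kick–drift–kick: half a velocity update with forces at
the current positions, a full position update (then boundary handling),
collision detection, pair forces and bimolecular triggers at the new
positions, then the second half kick with the recomputed forces. Because
positions do not change between the second half kick and the next first
kick, the pair forces computed in the collision phase are reused in the next
step's first kick — this is the standard KDK force reuse, and it is what the
instrumented loop-order test pins down. The thermal force is drawn once per
step and used in both half kicks; drawing twice would double the noise
power.

Friction placement in the kicks is a documented choice (the source scheme
is not specified): the default explicit form
`v ← v + (F − γv) Δt/2m` is guarded by `γΔt/m ≤ 0.1`, enforced through the
time step; the `semi_implicit` option
`v ← (v + F Δt/2m)/(1 + γΔt/2m)` is unconditionally stable and converges to
overdamped Brownian dynamics (displacement variance `2DΔt` per component)
when `γΔt/m ≫ 1`. The explicit mode is for resolving velocity statistics
(free-diffusion validation); the semi-implicit mode is what makes the
micro-second-scale scenarios affordable, and its diffusion constant is
exact in the high-friction limit up to `O(m/γΔt)`.

The adaptive step is `Δt = r_min / (v_max · g)` with granularity `g ≥ 1`,
clamped to `max_timestep`. In explicit mode `v_max` is floored by the
thermal speed `sqrt(k_B T / m)` of the lightest mobile particle so a cold
start does not produce an unbounded step. Two practical consequences are
worth knowing: a freshly created particle (radius/100) drags `r_min` and
hence `Δt` down ~100× until it grows, so scenario code that spawns products
*outside* existing particles (surface placement) spawns them at full size —
no overlap is created, and the ramp's purpose (avoiding overlap shock) is
moot; and immobile (anchored) species are excluded from `v_max`.

## 3. Collision detection

Only siblings (same parent) and a particle against its own parent's shell
interact; particles in different compartments never exert direct contact
forces — the shell mediates everything across compartment boundaries.
Overlap depths are `r_a + r_b − dist` for siblings and
`dist + r_a − r_parent` (the protrusion) for shell contacts. Detection runs
per containment group: exact all-pairs below 150 particles, a uniform cell
grid (edge ≥ 2 r_max, rebuilt every step, ghost-padded indices) above;
periodic domains use minimum-image all-pairs. The output is deterministic
(sorted by id pair) and is checked exactly — every pair, every depth —
against two independent brute-force oracles over thousands of random
configurations.

Ignore relations are consulted symmetrically and only exist while a
division is in flight; the acceptance suite asserts they are empty at every
completion.

## 4. What the scenarios emulate

* **Correctness suite** (`birth`, `decay`, `bimolecular`): systems with
  closed-form expectations. Birth counts are Poisson(k·t) exactly; decay
  survival is exactly `exp(−kt)` at step boundaries (the firing probability
  is the exact per-step survival complement); the diffusion-limited
  `A + B → C` box (10 nm reactants, volume fraction 7·10⁻⁴, periodic)
  reproduces the Smoluchowski rate. Numerical biases we accept: the trigger
  overlap `d* = 0.05 r` shrinks the effective absorbing distance by 2.5%,
  and finite-step crossings are occasionally missed; the 20% tolerance
  absorbs both. The initial-rate fit starts after `t = 10⁻⁴ s` because the
  transient Smoluchowski term `R/sqrt(πDt)` exceeds the tolerance earlier.
  The barrier experiment uses a deeper trigger (`d* = r/2`) and a step small
  enough that the diffusive displacement per step is ≈ 0.2 d*; with a
  shallow `d*` the barrier zone is crossed ballistically within one step
  and W has no effect — a genuine resolution requirement of the
  constant-force method, not a tuning knob.
* **Division fixture**: batches of spatially separated compartments
  dividing simultaneously at T = 0 with stiff walls (E = 10⁵ Pa), so cargo
  is dragged cleanly and settles inside the daughters; the per-step shell
  displacement (5 nm) stays below the cargo radius. T = 0 removes thermal
  jitter from the geometry audit without touching the stochastic content
  split, which is what the binomial criterion tests.
* **Vesicle transport**: geometry at stated scale (cell 2.5 µm, V₁ ≈ 0.118
  µm³ ≈ 9 V₂, 90%/10% SNARE split; control 0.065 µm³ each, 50%/50%), SNARE
  *counts* scaled by `scale` (desk fixtures use 0.01 → 1000 of each type).
  Budding rate is linear in compartment volume (the source states only a
  volume dependence); packets are 80% enriched in the coat type; coat is
  drawn from the compartment's composition; the budded vesicle appears just
  clear of the parent surface at full size. Volume moves conservatively:
  budding shrinks the source instantly by one vesicle volume and fusion
  restores it (`r³` additivity), so compartment volumes equalise and SNARE-X
  accumulates in compartment 1 under the directed field, while the
  control shows no sorting — the qualitative contrast the acceptance suite
  checks. Compartments and the cell are anchored (`mobile = FALSE`,
  abstracting cytoskeletal attachment); a fusion product inherits the
  anchored reactant's position, since a mass-weighted centroid would let
  hundreds of fusions walk a compartment off its pole.
* **Yeast colony**: cells are anchored 2D particles whose cell cycle is an
  attribute counter — 100 increments of 0.01 at base rate 100/7200 s⁻¹, so
  the unbound inter-division time is 120 min with CV 10% (a deliberately
  simple stand-in for a full protein-network oscillator, which is outside
  scope). Bound pheromone divides the increment rate by `1 + bound/50`
  (monotone inhibition is the tested property; the constant 50 is a model
  choice). Pheromones and Sxa2 diffuse, are absorbed at the border, bind
  opposite-type cells, and Sxa2 annihilates P-factor. The time-scale gap
  between sub-µs diffusion steps and the 7200 s cycle is inherent to the
  system; tests exercise the two regimes separately.
* **Lipid raft**: one static raft, area fraction exactly 25%, interior
  viscosity 10 η; 10 nm proteins; LRP entry barrier `W = 12·10⁻²¹ J`
  (≈ 2.8 k_BT at 310 K) over `d* = 2 r`; all exits free. CK1 accumulates
  because exit traverses the crossing zone at a 10× lower diffusion
  coefficient than entry — a kinetic-trapping effect, not an equilibrium
  potential; the tested property is the occupancy *ordering* CK1 > LRP,
  which is robust long before full steady state.

A green scenario test therefore establishes that the mechanisms compose
correctly at desk scale under the stated statistics — not that any
biological parameter is quantitatively realistic, and not behaviour at the
full published scale (10⁵ SNAREs, 900 simulated minutes), which interpreted
R cannot reach.

## 5. Numerical and API choices

* Strict SI internally; `nf_units` provides conversion constants.
* One global RNG stream seeded per state; thermal draws, reaction tests,
  splits, axes and tie-breaks consume it in a fixed order, so a
  (model, physics, seed) triple fixes the trajectory bit for bit. Snapshots
  serialize the stream (and all doubles at 17 significant digits), so
  load-and-continue equals the uninterrupted run exactly; loading a
  snapshot restores the stream, so runs of multiple states should not be
  interleaved if determinism matters.
* `d*` is an absolute length; `d_star_frac` is sugar for a fraction of the
  smaller radius of the pair, resolved at contact time.
* The division axis is a uniform random unit vector; content that cannot
  fit the smaller daughter produces a warning, not an error.
* Boundary modes: reflective (default), absorbing (removes a particle with
  its contents — yeast pheromones at the border), periodic (minimum-image).
  Contained particles are confined by their shell, not the box.
* Pure R, fully vectorised over particles and pairs; no compiled code. The
  acceptance workloads (≈ 10³ particles, ≈ 10⁴–10⁵ steps) run in seconds to
  a few minutes each; a compiled broad phase would be the first extension
  for larger systems.

## 6. Known limitations

Hydrodynamic interactions, rotation/torque, attractive potentials outside
the reaction machinery, non-spherical geometry, compartment fusion as
reverse division, and automatic conversion between the microscopic barrier
`W` and a macroscopic rate constant are all out of scope. The constant
reactive force requires steps resolving `d*` (see §4); the semi-implicit
integrator sacrifices velocity statistics for step size; and periodic
domains are only meaningful for flat (non-nested) systems, since a shell
cannot straddle a wrapped boundary.
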