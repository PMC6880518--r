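# nestforce

Particle-based reaction–diffusion simulation in which **everything is a
hollow sphere and every interaction is a force**. A protein, a vesicle, a
lipid raft, a whole cell — each is a particle with a position, radius,
density and an arbitrary attribute map, and particles may contain other
particles to any depth. Excluded volume, bimolecular reactions, particles
shuttling into and out of compartments, and the fission of a compartment
into two daughters are all mediated by pairwise forces and integrated
continuously, rather than executed as discrete jumps. Non-spatial chemistry
(e.g. a cell-cycle oscillator living inside one cell) runs alongside as
stochastic events on particle attributes, with rates given by arbitrary R
functions of those attributes.

The package is aimed at modellers of multi-level cell-biological systems —
endosomal traffic, dividing cell colonies, membrane microdomains — who need
compartment dynamics and crowding in the same simulation.

## The model

Every mobile particle follows the Langevin equation

```
m ẍ = −γ ẋ + f(t) + F_ext(x, t)
```

with Stokes friction `γ = 6π η r` (η resolved through the containment
hierarchy, so a raft interior can be 10× more viscous than the membrane),
a Gaussian thermal force with the fluctuation–dissipation variance
`σ² = 2 γ k_B T / Δt` per component (so `D = k_B T / γ` and MSD → 2 d D t),
and external force fields (e.g. a dipole-like field standing in for
motor-protein transport). Integration is kick–drift–kick with the adaptive
step `Δt = r_min / (v_max · g)`.

Forces:

| interaction | law |
|---|---|
| excluded volume | Hertz contact `F = (4/3) E* √(r_eff d³)` in the overlap depth `d` |
| reaction pair | constant `F = W / d*`; the reaction triggers at overlap `d > d*`, so the work to react is exactly `W` |
| nesting / unnesting | same reactive force; triggers at full containment / full exit, with no positional jump |
| compartment fission | `F = m_i · a` on every member of each half, giving the halves uniform motion; daughters' radii interpolate with separation, and temporary *ignore relations* suppress the unphysical daughter–daughter contact |

Zeroth- and first-order reactions (creation, decay, attribute updates,
radius changes, division triggers) are sampled stochastically per step with
user-defined propensity functions `λ(attributes, contents)`; a
diffusion-limited `A + B → C` run reproduces the Smoluchowski rate
`4π (D_A + D_B)(r_A + r_B)` within the fit tolerance.

## Worked example: selective lipid-raft entry

Two membrane proteins diffuse in a 2D membrane patch containing one static
raft (25% of the area, 10× interior viscosity). CK1-γ enters the raft
freely; LRP 5/6 must cross an energy barrier of 12·10⁻²¹ J:

```r
library(nestforce)
fx <- scenario_raft(seed = 7, n_each = 50)
st <- fx$state
for (k in 1:6) {
  run_steps(st, 500)
  cts <- raft_counts(st)
  cat(sprintf("t = %.2e s  in-raft: LRP = %d  CK1 = %d\n",
              st$time, cts["LRP"], cts["CK1"]))
}
```

```
t = 2.75e-04 s  in-raft: LRP = 0  CK1 = 0
t = 5.50e-04 s  in-raft: LRP = 0  CK1 = 0
t = 8.25e-04 s  in-raft: LRP = 0  CK1 = 1
t = 1.10e-03 s  in-raft: LRP = 0  CK1 = 1
t = 1.37e-03 s  in-raft: LRP = 1  CK1 = 2
t = 1.65e-03 s  in-raft: LRP = 1  CK1 = 6
```

The zero-barrier species accumulates first (slow interior diffusion traps
entrants), while the barrier suppresses LRP entry — the occupancy ordering
the validation suite tests over many seeds. The mobility change on nesting
is exact Stokes–Einstein bookkeeping:

```r
out_p <- st$id[st$species == "CK1" & st$parent == 0L][1]
in_p  <- st$id[st$species == "CK1" & st$parent != 0L][1]
cat(sprintf("D membrane = %.3e m2/s, D raft = %.3e m2/s\n",
    diffusion_coefficient(st, out_p), diffusion_coefficient(st, in_p)))
#> D membrane = 2.271e-11 m2/s, D raft = 2.271e-12 m2/s
```

Other packaged scenarios (`list_scenarios()`): `birth`, `decay` and
`bimolecular` correctness fixtures, `free_diffusion`, `division`,
`vesicle` (directed SNARE sorting vs Brownian control), `yeast`
(attribute-based cell cycle, pheromone inhibition, fission) and `raft`.
From the command line:

```sh
Rscript -e 'nestforce::nestforce_main()' run raft --seed 1 --steps 500 --out out/
Rscript -e 'nestforce::nestforce_main()' validate
```

which writes a species-counts CSV, an extended-XYZ trajectory and a JSON
snapshot that restores bit-identical runs (`load_snapshot()`).

## Scope notes

Compartment *fusion* as the reverse of division, automatic conversion of the
microscopic barrier `W` to a macroscopic rate constant, GPU collision
detection and live visualisation are out of scope. See the methods vignette
(`vignettes/nestforce-methods.Rmd`) for the model's assumptions, parameter
choices and limitations.
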