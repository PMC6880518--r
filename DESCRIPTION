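Package: nestforce
Title: Force-Based Simulation of Dynamically Nested Particles
Version: 0.1.0
Authors@R:
    person("nestforce", "developers", email = "nestforce@example.org",
           role = c("aut", "cre"))
Description: A particle-based reaction-diffusion simulator in which every
    entity, from a protein to a cell, is a hollow sphere propagated by the
    Langevin equation. Excluded volumes (Hertz soft-sphere contact),
    bimolecular reactions (constant reactive forces with a microscopic
    energy barrier), dynamic nesting and un-nesting of particles, and the
    continuous fission of compartments are all mediated by forces, while
    zeroth- and first-order reactions (including non-spatial intra-particle
    dynamics on arbitrary attributes) are sampled stochastically with
    user-defined rate functions. Ships rule builders, a kick-drift-kick
    integrator with adaptive time step, hierarchical collision detection,
    scenario fixtures (birth/decay/bimolecular correctness suite, vesicular
    transport, yeast colony, lipid raft), observers, and text-based output
    formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
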