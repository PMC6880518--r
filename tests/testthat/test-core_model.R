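test_that("species registration validates names, schema and physical defaults", {
  m <- new_model(3)
  sp <- register_species(m, "Cell", radius = 4e-6, density = 1000,
                         attributes = list(phase = "G1", cycM = 0))
  expect_s3_class(sp, "nf_species")
  expect_identical(unname(sp$kinds), c("string", "number"))
  expect_error(register_species(m, "Cell", radius = 1e-6),
               "already registered")
  expect_error(register_species(m, "X", radius = 0), "default_radius")
  expect_error(register_species(m, "X", radius = 1e-6, density = 0),
               "default_density")
  expect_error(register_species(m, "X", radius = 1e-6, poisson_ratio = 0.5),
               "poisson_ratio")
  expect_error(register_species(m, "X", radius = 1e-6, young_modulus = 0),
               "elastic_modulus")
  expect_error(register_species(m, "X", radius = 1e-6,
                                attributes = list(a = 1, a = 2)), "unique")
  expect_error(register_species(m, "X", radius = 1e-6,
                                attributes = list(f = sin)), "kind")
})

test_that("spawning fills the schema, validates placement and parent fit", {
  m <- new_model(3)
  register_species(m, "V", radius = 5e-8, density = 1000,
                   attributes = list(coat = "X"))
  register_species(m, "Cont", radius = 1e-6)
  ph <- physics_params(domain_lo = rep(0, 3), domain_hi = rep(1e-5, 3))
  st <- new_state(m, ph, 1)
  id <- spawn_particle(st, "V", rep(5e-6, 3), attrs = list(coat = "Y"))
  expect_identical(p_attr(st, id, "coat"), "Y")
  expect_identical(p_parent(st, id), 0L)
  expect_error(spawn_particle(st, "nope", rep(5e-6, 3)), "unknown species")
  expect_error(spawn_particle(st, "V", rep(2e-5, 3)), "outside")
  expect_error(spawn_particle(st, "V", rep(5e-6, 3),
                              attrs = list(coat = 1)), "kind")
  expect_error(spawn_particle(st, "V", rep(5e-6, 3),
                              attrs = list(bogus = 1)), "schema")
  cont <- spawn_particle(st, "Cont", rep(2e-6, 3))
  # final-size sphere must fit inside the parent: offset + r > r_parent fails
  expect_error(
    spawn_particle(st, "V", rep(2e-6, 3) + c(2e-6, 0, 0), parent = cont),
    "does not fit")
  inner <- spawn_particle(st, "V", rep(2e-6, 3) + c(5e-7, 0, 0),
                          parent = cont)
  expect_identical(p_parent(st, inner), cont)
})

test_that("creation-reaction spawns start tiny and ramp to the target", {
  st <- tiny_state()
  id <- spawn_particle(st, "A", rep(5e-5, 3), grown = FALSE)
  row <- match(id, st$id)
  expect_equal(st$radius[row], 1e-6 / 100)
  expect_equal(st$target_radius[row], 1e-6)
  total <- 0
  while (st$radius[row] < st$target_radius[row]) {
    grow_step(st, 1e-4)
    total <- total + 1e-4
  }
  expect_equal(st$radius[row], 1e-6)  # clamped exactly at target
  expect_lte(total, st$phys$growth_time + 1e-4)
})

test_that("mass follows solid-sphere (3D) and unit-slab (2D) conventions", {
  expect_equal(particle_mass(1e-6, 1000, 3), 4.18879e-15, tolerance = 1e-5)
  expect_equal(particle_mass(2e-6, 1000, 3) / particle_mass(1e-6, 1000, 3), 8)
  expect_equal(particle_mass(1e-6, 1000, 2), 1000 * pi * 1e-12)
  expect_error(particle_mass(1e-6, 0, 3))
})

test_that("local viscosity resolves through the ancestor chain", {
  m <- new_model(3)
  register_species(m, "P", radius = 2e-9)
  register_species(m, "Raft", radius = 1e-6, interior_viscosity = 1e-2)
  register_species(m, "Cell", radius = 5e-6, interior_viscosity = 2e-3)
  register_species(m, "Bag", radius = 2e-6)   # inherits
  ph <- physics_params(viscosity = 1e-3,
                       domain_lo = rep(0, 3), domain_hi = rep(1e-4, 3))
  st <- new_state(m, ph, 1)
  top <- spawn_particle(st, "P", rep(5e-5, 3))
  cell <- spawn_particle(st, "Cell", rep(2e-5, 3))
  raft <- spawn_particle(st, "Raft", rep(2e-5, 3), parent = cell)
  bag <- spawn_particle(st, "Bag", rep(2e-5, 3), parent = cell)
  in_raft <- spawn_particle(st, "P", rep(2e-5, 3), parent = raft)
  in_bag <- spawn_particle(st, "P", rep(2e-5, 3), parent = bag)
  expect_equal(local_viscosity(st, top), 1e-3)
  expect_equal(local_viscosity(st, in_raft), 1e-2)   # innermost definer
  expect_equal(local_viscosity(st, in_bag), 2e-3)    # walk past "inherit"
})

test_that("Stokes-Einstein: gamma = 6 pi eta r and D * gamma = kB T exactly", {
  st <- tiny_state()
  id <- spawn_particle(st, "A", rep(5e-5, 3))
  expect_equal(friction_coefficient(st, id), 6 * pi * 1e-3 * 1e-6,
               tolerance = 1e-12)
  expect_equal(diffusion_coefficient(st, id), 2.2706e-13, tolerance = 1e-4)
  # identity to machine precision for a spread of radii
  for (r in c(2e-9, 5e-8, 1e-6, 4e-6)) {
    p <- spawn_particle(st, "A", rep(4e-5, 3), radius = r)
    expect_equal(diffusion_coefficient(st, p) * friction_coefficient(st, p),
                 st$phys$kB * st$phys$temperature, tolerance = 1e-14)
  }
  st0 <- tiny_state(temperature = 0)
  p0 <- spawn_particle(st0, "A", rep(5e-5, 3))
  expect_identical(diffusion_coefficient(st0, p0), 0)
})

test_that("containment forest: reparent, children, is_ancestor, cycle guard", {
  m <- new_model(3)
  register_species(m, "Cell", radius = 5e-6)
  register_species(m, "Raft", radius = 2e-6)
  register_species(m, "P", radius = 1e-8)
  ph <- physics_params(domain_lo = rep(0, 3), domain_hi = rep(1e-4, 3))
  st <- new_state(m, ph, 1)
  cell <- spawn_particle(st, "Cell", rep(2e-5, 3))
  raft <- spawn_particle(st, "Raft", rep(2e-5, 3), parent = cell)
  p <- spawn_particle(st, "P", rep(2e-5, 3), parent = raft)
  expect_true(is_ancestor(st, cell, p))     # transitive
  expect_true(is_ancestor(st, raft, p))
  expect_false(is_ancestor(st, p, cell))
  expect_identical(children(st, cell), raft)
  expect_error(reparent(st, cell, p), "cycle")
  expect_error(reparent(st, cell, cell), "cycle")
  reparent(st, p, 0L)
  expect_true(p %in% children(st, 0L))
  expect_silent(audit_forest(st))
  expect_length(audit_containment(st), 0L)
  expect_error(reparent(st, p, 999L), "unknown")
})

test_that("attribute mutation is schema-checked", {
  m <- new_model(3)
  register_species(m, "C", radius = 1e-6,
                   attributes = list(n = 0, tag = "a", ok = TRUE))
  ph <- physics_params(domain_lo = rep(0, 3), domain_hi = rep(1e-4, 3))
  st <- new_state(m, ph, 1)
  id <- spawn_particle(st, "C", rep(5e-5, 3))
  p_set_attr(st, id, "n", 5)
  expect_identical(p_attr(st, id, "n"), 5)
  expect_error(p_set_attr(st, id, "n", "five"), "kind")
  expect_error(p_set_attr(st, id, "missing", 1), "schema")
})
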