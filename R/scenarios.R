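# regular lattice of n points inside [lo, hi]^dim with a margin, used to place
# non-interacting initial conditions reproducibly
.nf_lattice <- function(n, lo, hi, dim) {
  k <- ceiling(n^(1 / dim))
  ax <- lapply(seq_len(dim), function(j)
    lo[j] + (seq_len(k) - 0.5) * (hi[j] - lo[j]) / k)
  g <- as.matrix(do.call(expand.grid, ax))
  dimnames(g) <- NULL
  g[seq_len(n), , drop = FALSE]
}

#' Correctness-suite scenarios: birth, decay, bimolecular
#'
#' Minimal reaction systems with closed-form expectations, used to validate
#' the stochastic machinery against theory: a zeroth-order birth process
#' (Poisson counts), first-order decay (exponential survival) and the
#' irreversible/reversible bimolecular reaction A + B <-> C, whose
#' diffusion-limited forward rate is compared against the Smoluchowski
#' encounter rate `4 pi (D_A + D_B)(r_A + r_B)`.
#'
#' @param seed RNG seed.
#' @param k birth rate (1/s) or decay rate (1/s).
#' @param t_step engine time step (s); reactions are exact in `dt` (birth
#'   events are Poisson-sampled, decay survival is exactly exponential at step
#'   boundaries), so the step size only sets the sampling resolution.
#' @return an `nf_state` ready to run.
#' @export
scenario_birth <- function(seed = 1L, k = 10, t_step = 0.1) {
  m <- new_model(3, contact = FALSE)
  register_species(m, "A", radius = 1e-7, density = 1000)
  add_rule(m, rule_zeroth("A", rate = k))
  ph <- physics_params(temperature = 0, viscosity = 1e-3,
                       max_timestep = t_step, granularity = 1,
                       domain_lo = rep(0, 3), domain_hi = rep(1e-5, 3),
                       growth_time = t_step * 5,
                       friction_mode = "semi_implicit")
  new_state(m, ph, seed)
}

#' @rdname scenario_birth
#' @param n0 initial particle count.
#' @export
scenario_decay <- function(seed = 1L, n0 = 1000, k = 1, t_step = 0.05) {
  m <- new_model(3, contact = FALSE)
  register_species(m, "A", radius = 1e-7, density = 1000)
  add_rule(m, rule_first("A", rate = k,
                         post = function(state, id)
                           remove_particles(state, id)))
  ph <- physics_params(temperature = 0, viscosity = 1e-3,
                       max_timestep = t_step, granularity = 1,
                       domain_lo = rep(0, 3), domain_hi = rep(1e-5, 3),
                       friction_mode = "semi_implicit")
  st <- new_state(m, ph, seed)
  pts <- .nf_lattice(n0, ph$domain_lo, ph$domain_hi, 3)
  for (i in seq_len(n0)) spawn_particle(st, "A", pts[i, ])
  st
}

#' @rdname scenario_birth
#' @param n_each initial count of A and of B.
#' @param radius reactant radius (m); products get the volume-conserving
#'   radius automatically.
#' @param box edge length (m) of the periodic cubic box.
#' @param W energy barrier (J) of the forward reaction; 0 is diffusion
#'   limited.
#' @param d_star_frac required overlap as a fraction of the reactant radius
#'   (kept small so the effective absorbing distance stays close to
#'   r_A + r_B).
#' @param reversible add the backward reaction C -> A + B at rate `k_back`.
#' @param k_back backward rate (1/s).
#' @export
scenario_bimolecular <- function(seed = 1L, n_each = 50, radius = 1e-8,
                                 box = 8.3e-7, W = 0, d_star_frac = 0.05,
                                 reversible = FALSE, k_back = 50,
                                 t_step = 2.2e-8) {
  m <- new_model(3, contact = TRUE)
  register_species(m, "A", radius = radius, density = 1000)
  register_species(m, "B", radius = radius, density = 1000)
  register_species(m, "C", radius = radius * 2^(1 / 3), density = 1000)
  add_rule(m, rule_bimolecular("A", "B", kind = "fuse", product = "C",
                               d_star = d_star_frac * radius, W = W))
  if (reversible) {
    gap <- 0.05 * radius
    add_rule(m, rule_first("C", rate = k_back, post = function(state, id) {
      pos <- p_position(state, id)
      dir <- .nf_runif_dir(state$dim)
      remove_particles(state, id)
      ida <- spawn_particle(state, "A", pos, check_fit = FALSE)
      spawn_particle(state, "B",
                     pos + dir * (2 * radius + gap), check_fit = FALSE)
      invisible(ida)
    }))
  }
  ph <- physics_params(temperature = 310, viscosity = 1e-3,
                       max_timestep = t_step, granularity = 1,
                       domain_lo = rep(0, 3), domain_hi = rep(box, 3),
                       boundary = "periodic", friction_mode = "semi_implicit")
  st <- new_state(m, ph, seed)
  for (i in seq_len(n_each)) {
    spawn_particle(st, "A", stats::runif(3, 0, box))
    spawn_particle(st, "B", stats::runif(3, 0, box))
  }
  st
}

#' Free-diffusion reference scenario
#'
#' Non-interacting spheres on a sparse lattice in a large reflective box,
#' integrated with the explicit-friction kick-drift-kick scheme at
#' `gamma dt / m ~ 0.02` so both the velocity equilibrium (variance kB T / m
#' per component) and the long-time mean squared displacement (6 D t in 3D)
#' are resolved.
#'
#' @param seed RNG seed.
#' @param n number of particles.
#' @param radius particle radius (m).
#' @param temperature temperature (K).
#' @param viscosity medium viscosity (Pa.s).
#' @return an `nf_state`.
#' @export
scenario_free_diffusion <- function(seed = 1L, n = 1000, radius = 1e-6,
                                    temperature = 310, viscosity = 1e-3) {
  m <- new_model(3, contact = FALSE)
  register_species(m, "T", radius = radius, density = 1000)
  gamma <- 6 * pi * viscosity * radius
  mass <- particle_mass(radius, 1000, 3)
  ph <- physics_params(temperature = temperature, viscosity = viscosity,
                       max_timestep = 0.02 * mass / gamma, granularity = 1,
                       domain_lo = rep(0, 3), domain_hi = rep(4.4e-5, 3))
  st <- new_state(m, ph, seed)
  pts <- .nf_lattice(n, ph$domain_lo + 2e-6, ph$domain_hi - 2e-6, 3)
  for (i in seq_len(n)) spawn_particle(st, "T", pts[i, ])
  st
}

#' Compartment-division fixture
#'
#' A single compartment holding `n_content` cargo particles, plus the division
#' rule that splits it (a = 2250 m/s^2, volume-halving children). The rule's
#' spontaneous rate is zero: tests start the fission explicitly with
#' [start_division()] and then run the engine until the transition completes.
#' Run at T = 0 with stiff species (E = 1e5 Pa) so cargo is dragged cleanly by
#' the shells and settles inside the children.
#'
#' @param seed RNG seed.
#' @param n_content number of contained cargo particles per compartment;
#'   vectorised — giving a vector builds one compartment per entry, spaced on
#'   a lattice so the divisions proceed independently in a single engine run.
#' @return list with the state, the compartment ids and the division rule.
#' @export
scenario_division <- function(seed = 1L, n_content = 10L) {
  m <- new_model(3, contact = TRUE)
  register_species(m, "Comp", radius = 1e-6, density = 1000,
                   young_modulus = 1e5)
  register_species(m, "Cargo", radius = 5e-8, density = 1000,
                   young_modulus = 1e5)
  rule <- rule_divide("Comp", rate = 0, a_division = 2250)
  add_rule(m, rule)
  k <- length(n_content)
  span <- 5e-6 * ceiling(k^(1 / 3))
  ph <- physics_params(temperature = 0, viscosity = 1e-3,
                       max_timestep = 1e-5, granularity = 1,
                       domain_lo = rep(0, 3), domain_hi = rep(span, 3),
                       friction_mode = "semi_implicit", tol_contain = 5e-9)
  st <- new_state(m, ph, seed)
  centers <- .nf_lattice(k, ph$domain_lo, ph$domain_hi, 3)
  comps <- integer(k)
  for (j in seq_len(k)) {
    comps[j] <- spawn_particle(st, "Comp", centers[j, ])
    for (i in seq_len(n_content[j])) {
      pos <- centers[j, ] + .nf_runif_ball(3) * (1e-6 - 6e-8)
      spawn_particle(st, "Cargo", pos, parent = comps[j])
    }
  }
  list(state = st, comp = comps, rule = rule)
}
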