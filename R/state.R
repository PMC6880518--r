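#' Physics parameters
#'
#' Global physical settings of a simulation: thermodynamics, the simulation
#' box, time-step control and numerical tolerances. All values are strict SI.
#'
#' @param temperature system temperature (K), >= 0.
#' @param viscosity dynamic viscosity of the medium (Pa.s), > 0.
#' @param granularity dimensionless precision parameter g >= 1 of the adaptive
#'   time step dt = r_min / (v_max * g); larger g means smaller steps.
#' @param max_timestep hard upper bound on the time step (s).
#' @param domain_lo,domain_hi axis-aligned box extents (m), length equal to the
#'   model dimension.
#' @param boundary `"reflective"` (mirror positions, flip normal velocity),
#'   `"absorbing"` (particles crossing the boundary are removed together with
#'   their contents) or `"periodic"` (wrap; pair distances use the
#'   minimum-image convention).
#' @param tol_contain tolerance (m) on the containment geometry invariant.
#' @param growth_time duration (s) of continuous radius ramps (particle
#'   creation, explicit radius changes, budding).
#' @param friction_mode `"explicit"` integrates friction explicitly in the
#'   kicks with a stability guard `gamma*dt/m <= 0.1`; `"semi_implicit"` uses
#'   the unconditionally stable form `v <- (v + F dt/2m) / (1 + gamma dt/2m)`,
#'   which converges to overdamped Brownian dynamics for large `gamma*dt/m`.
#' @param kB Boltzmann constant (J/K); overridable for reduced-unit toy runs.
#' @return an `nf_physics` list.
#' @export
physics_params <- function(temperature = 310, viscosity = 1e-3,
                           granularity = 10, max_timestep = 1e-3,
                           domain_lo, domain_hi,
                           boundary = c("reflective", "absorbing", "periodic"),
                           tol_contain = 1e-12, growth_time = 1e-3,
                           friction_mode = c("explicit", "semi_implicit"),
                           kB = nf_kB) {
  boundary <- match.arg(boundary)
  friction_mode <- match.arg(friction_mode)
  stopifnot(temperature >= 0, viscosity > 0, granularity >= 1,
            max_timestep > 0, tol_contain > 0, growth_time > 0,
            length(domain_lo) == length(domain_hi), all(domain_hi > domain_lo))
  structure(list(temperature = temperature, viscosity = viscosity,
                 granularity = granularity, max_timestep = max_timestep,
                 domain_lo = as.numeric(domain_lo),
                 domain_hi = as.numeric(domain_hi), boundary = boundary,
                 tol_contain = tol_contain, growth_time = growth_time,
                 friction_mode = friction_mode, kB = kB),
            class = "nf_physics")
}

#' Create a simulation state
#'
#' The single mutable simulation object: particle store (flat, vectorised),
#' containment forest (parent links by particle id, 0 denoting the medium),
#' physics parameters and the seeded RNG. All stochastic draws of a run come
#' from R's global RNG stream, seeded here, so that a (model, physics, seed)
#' triple fixes the trajectory bit for bit.
#'
#' @param model an `nf_model`.
#' @param physics an `nf_physics`.
#' @param seed integer RNG seed.
#' @return an `nf_state` environment.
#' @export
new_state <- function(model, physics, seed = 1L) {
  stopifnot(inherits(model, "nf_model"), inherits(physics, "nf_physics"))
  if (length(physics$domain_lo) != model$dimension)
    stop("domain extents do not match the model dimension", call. = FALSE)
  set.seed(as.integer(seed))
  st <- new.env(parent = emptyenv())
  st$model <- model
  st$phys <- physics
  st$dim <- model$dimension
  st$time <- 0
  st$dt <- physics$max_timestep
  st$nsteps <- 0L
  st$next_id <- 1L
  st$seed <- as.integer(seed)
  n0 <- 0L
  st$id <- integer(n0)
  st$species <- character(n0)
  st$pos <- matrix(numeric(0), 0L, st$dim)
  st$vel <- matrix(numeric(0), 0L, st$dim)
  st$radius <- numeric(n0)
  st$target_radius <- numeric(n0)
  st$ramp_rate <- numeric(n0)
  st$density <- numeric(n0)
  st$parent <- integer(n0)          # parent id, 0 = medium
  st$attrs <- list()
  st$ignore <- list()               # per particle: ids whose contacts are suppressed
  st$reacted <- logical(n0)
  st$in_transition <- logical(n0)
  st$mobile <- logical(n0)
  st$pair_force <- matrix(numeric(0), 0L, st$dim)
  st$transitions <- list()
  st$n <- 0L
  class(st) <- "nf_state"
  st
}

#' @export
print.nf_state <- function(x, ...) {
  cat(sprintf("<nf_state> t = %g s, %d particles, %d species, dim %d\n",
              x$time, x$n, length(x$model$species), x$dim))
  invisible(x)
}

.nf_row <- function(state, id) {
  r <- match(id, state$id)
  if (anyNA(r)) stop("unknown particle id: ",
                     paste(id[is.na(r)], collapse = ", "), call. = FALSE)
  r
}

.nf_inside_domain <- function(state, position) {
  all(position >= state$phys$domain_lo) && all(position <= state$phys$domain_hi)
}

#' Spawn a particle
#'
#' Adds a particle to the store. Particles created as part of initial
#' conditions appear at full size (`grown = TRUE`); particles created by
#' reactions appear as very small spheres (1/100 of the target radius) and
#' grow continuously to their target over `growth_time` (see [grow_step()]),
#' which avoids sudden overlaps and the numerical heating they would cause.
#'
#' @param state an `nf_state`.
#' @param species species name.
#' @param position length-`dimension` position (m); must lie inside the domain
#'   for top-level particles.
#' @param parent containing particle id, or 0 for the medium. The final-size
#'   sphere must fit inside the parent.
#' @param radius radius override (m); default from the species.
#' @param attrs attribute overrides (validated against the schema).
#' @param velocity initial velocity (m/s), default zero.
#' @param grown if `FALSE`, start at 1/100 of the target radius and ramp.
#' @param check_fit internal: skip the fits-inside-parent/domain check (used
#'   by division and fusion placement, where transient breaches are resolved
#'   by contact forces).
#' @return the new particle id.
#' @export
spawn_particle <- function(state, species, position, parent = 0L,
                           radius = NULL, attrs = list(), velocity = NULL,
                           grown = TRUE, check_fit = TRUE) {
  sp <- state$model$species[[species]]
  if (is.null(sp)) stop("unknown species: '", species, "'", call. = FALSE)
  position <- as.numeric(position)
  stopifnot(length(position) == state$dim)
  r_target <- if (is.null(radius)) sp$radius else radius
  stopifnot(r_target > 0)
  parent <- as.integer(parent)
  if (parent == 0L) {
    if (check_fit && !.nf_inside_domain(state, position))
      stop("position outside the simulation domain", call. = FALSE)
  } else {
    pr <- .nf_row(state, parent)
    off <- sqrt(sum((position - state$pos[pr, ])^2))
    if (check_fit && off + r_target > state$radius[pr] + state$phys$tol_contain)
      stop("particle does not fit inside its parent (offset ", off,
           " + radius ", r_target, " > ", state$radius[pr], ")", call. = FALSE)
  }
  a <- sp$attributes
  if (length(attrs)) {
    bad <- setdiff(names(attrs), names(a))
    if (length(bad)) stop("attributes not in schema of '", species, "': ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (nm in names(attrs)) {
      if (.nf_kind_of(attrs[[nm]]) != sp$kinds[[nm]])
        stop("attribute '", nm, "' must be of kind ", sp$kinds[[nm]],
             call. = FALSE)
      a[[nm]] <- attrs[[nm]]
    }
  }
  id <- state$next_id
  state$next_id <- id + 1L
  n <- state$n + 1L
  r0 <- if (grown) r_target else r_target / 100
  state$id <- c(state$id, id)
  state$species <- c(state$species, species)
  state$pos <- rbind(state$pos, position)
  state$vel <- rbind(state$vel,
                     if (is.null(velocity)) numeric(state$dim) else velocity)
  state$radius <- c(state$radius, r0)
  state$target_radius <- c(state$target_radius, r_target)
  state$ramp_rate <- c(state$ramp_rate,
                       if (grown) 0 else (r_target - r0) / state$phys$growth_time)
  state$density <- c(state$density, sp$density)
  state$parent <- c(state$parent, parent)
  state$attrs[[n]] <- a
  state$ignore[[n]] <- integer(0)
  state$reacted <- c(state$reacted, TRUE)  # no reaction in the creation step
  state$in_transition <- c(state$in_transition, FALSE)
  state$mobile <- c(state$mobile, sp$mobile)
  state$pair_force <- rbind(state$pair_force, numeric(state$dim))
  state$n <- n
  dimnames(state$pos) <- NULL
  dimnames(state$vel) <- NULL
  dimnames(state$pair_force) <- NULL
  id
}

.nf_keep_rows <- function(state, keep) {
  state$id <- state$id[keep]
  state$species <- state$species[keep]
  state$pos <- state$pos[keep, , drop = FALSE]
  state$vel <- state$vel[keep, , drop = FALSE]
  state$radius <- state$radius[keep]
  state$target_radius <- state$target_radius[keep]
  state$ramp_rate <- state$ramp_rate[keep]
  state$density <- state$density[keep]
  state$parent <- state$parent[keep]
  state$attrs <- state$attrs[keep]
  state$ignore <- state$ignore[keep]
  state$reacted <- state$reacted[keep]
  state$in_transition <- state$in_transition[keep]
  state$mobile <- state$mobile[keep]
  state$pair_force <- state$pair_force[keep, , drop = FALSE]
  state$n <- sum(keep)
  invisible(state)
}

#' Remove particles (with their contents)
#'
#' @param state an `nf_state`.
#' @param ids particle ids to remove; all transitive contents are removed too.
#' @export
remove_particles <- function(state, ids) {
  if (!length(ids)) return(invisible(state))
  gone <- as.integer(ids)
  repeat {
    more <- state$id[state$parent %in% gone & !(state$id %in% gone)]
    if (!length(more)) break
    gone <- c(gone, more)
  }
  keep <- !(state$id %in% gone)
  .nf_keep_rows(state, keep)
  # purge dangling ignore links
  state$ignore <- lapply(state$ignore, function(v) v[!(v %in% gone)])
  invisible(state)
}

#' Mass of a particle
#'
#' Hollow spheres are weighed as solid spheres of their density (no shell
#' thickness is defined). In 2D a unit slab thickness of 1 m is used by
#' convention, so mass = rho * pi * r^2.
#'
#' @param radius radius (m), vectorised.
#' @param density mass density (kg/m^3).
#' @param dimension 2 or 3.
#' @return mass (kg).
#' @export
particle_mass <- function(radius, density, dimension = 3) {
  stopifnot(all(radius > 0), all(density > 0))
  if (dimension == 3L) density * (4 / 3) * pi * radius^3
  else density * pi * radius^2
}

.nf_masses <- function(state, rows = seq_len(state$n)) {
  particle_mass(state$radius[rows], state$density[rows], state$dim)
}

#' Local viscosity, friction and diffusion coefficients
#'
#' The viscosity a particle experiences is the `interior_viscosity` of the
#' innermost ancestor that defines one (compartments may declare a distinct
#' interior, e.g. a lipid raft 10x more viscous than the membrane), falling
#' back to the medium viscosity. Friction follows Stokes drag,
#' `gamma = 6 pi eta r` (kept in 2D as well, where no clean Stokes analogue
#' exists), and diffusion the Stokes-Einstein relation `D = kB T / gamma`, so
#' `D * gamma = kB T` holds identically.
#'
#' @param state an `nf_state`.
#' @param id particle id (vectorised).
#' @return viscosity (Pa.s), friction (kg/s) or diffusion coefficient (m^2/s).
#' @export
local_viscosity <- function(state, id) {
  vapply(id, function(one) {
    p <- state$parent[.nf_row(state, one)]
    hops <- 0L
    while (p != 0L) {
      r <- match(p, state$id)
      if (is.na(r)) stop("broken parent link: particle ", one,
                         " has unknown ancestor ", p, call. = FALSE)
      eta <- state$model$species[[state$species[r]]]$interior_viscosity
      if (!is.null(eta)) return(eta)
      p <- state$parent[r]
      hops <- hops + 1L
      if (hops > state$n) stop("containment cycle detected", call. = FALSE)
    }
    state$phys$viscosity
  }, numeric(1))
}

#' @rdname local_viscosity
#' @export
friction_coefficient <- function(state, id) {
  rows <- .nf_row(state, id)
  6 * pi * local_viscosity(state, id) * state$radius[rows]
}

#' @rdname local_viscosity
#' @export
diffusion_coefficient <- function(state, id) {
  state$phys$kB * state$phys$temperature / friction_coefficient(state, id)
}

# per-row friction for the integrator hot path: vectorised level-by-level
# ancestor walk resolving each particle's interior viscosity
.nf_frictions <- function(state) {
  eta <- rep(state$phys$viscosity, state$n)
  if (any(state$parent != 0L)) {
    ivisc <- vapply(state$model$species, function(sp)
      if (is.null(sp$interior_viscosity)) NA_real_
      else sp$interior_viscosity, numeric(1))
    prow <- match(state$parent, state$id)     # NA for top level
    pending <- which(!is.na(prow))
    level <- prow[pending]
    guard <- 0L
    while (length(pending)) {
      v <- ivisc[state$species[level]]
      hit <- !is.na(v)
      eta[pending[hit]] <- v[hit]
      pending <- pending[!hit]
      level <- prow[level[!hit]]
      keep <- !is.na(level)
      pending <- pending[keep]
      level <- level[keep]
      guard <- guard + 1L
      if (guard > state$n) stop("containment cycle detected", call. = FALSE)
    }
  }
  6 * pi * eta * state$radius
}

#' Containment forest operations
#'
#' @param state an `nf_state`.
#' @param id,new_parent,a,b particle ids (`new_parent` may be 0, the medium).
#' @return `reparent()` the state invisibly; `children()` an id vector;
#'   `is_ancestor()` a logical (is `a` an ancestor of `b`?).
#' @export
reparent <- function(state, id, new_parent) {
  row <- .nf_row(state, id)
  new_parent <- as.integer(new_parent)
  if (new_parent != 0L) {
    .nf_row(state, new_parent)
    if (new_parent == id || is_ancestor(state, id, new_parent))
      stop("reparenting would create a containment cycle", call. = FALSE)
  }
  state$parent[row] <- new_parent
  invisible(state)
}

#' @rdname reparent
#' @export
children <- function(state, id) state$id[state$parent == as.integer(id)]

#' @rdname reparent
#' @export
is_ancestor <- function(state, a, b) {
  a <- as.integer(a)
  p <- state$parent[.nf_row(state, b)]
  hops <- 0L
  while (p != 0L) {
    if (p == a) return(TRUE)
    p <- state$parent[match(p, state$id)]
    hops <- hops + 1L
    if (hops > state$n) stop("containment cycle detected", call. = FALSE)
  }
  FALSE
}

#' State invariant audits
#'
#' `audit_forest()` walks every parent chain with a visited set and errors on
#' cycles or dangling links. `audit_containment()` returns the ids of
#' contained particles violating |x - x_parent| + r <= r_parent + tol, skipping
#' particles in a registered transition and particles whose shell overlap is
#' mediated by an unnest rule (they are legitimately crossing the shell).
#'
#' @param state an `nf_state`.
#' @return `audit_forest()` TRUE invisibly; `audit_containment()` an id vector
#'   (empty when the invariant holds).
#' @export
audit_forest <- function(state) {
  for (i in seq_len(state$n)) {
    seen <- integer(0)
    p <- state$parent[i]
    while (p != 0L) {
      if (p %in% seen) stop("containment cycle at particle ", state$id[i],
                            call. = FALSE)
      seen <- c(seen, p)
      r <- match(p, state$id)
      if (is.na(r)) stop("dangling parent id ", p, " at particle ",
                         state$id[i], call. = FALSE)
      p <- state$parent[r]
    }
  }
  invisible(TRUE)
}

#' @rdname audit_forest
#' @export
audit_containment <- function(state) {
  bad <- integer(0)
  nested <- which(state$parent != 0L & !state$in_transition)
  if (!length(nested)) return(bad)
  prow <- match(state$parent[nested], state$id)
  off <- sqrt(rowSums((state$pos[nested, , drop = FALSE] -
                       state$pos[prow, , drop = FALSE])^2))
  over <- off + state$radius[nested] -
    state$radius[prow] - state$phys$tol_contain
  for (k in which(over > 0)) {
    i <- nested[k]
    if (!.nf_has_unnest_rule(state, i, prow[k])) bad <- c(bad, state$id[i])
  }
  bad
}

.nf_has_unnest_rule <- function(state, row_inner, row_shell) {
  for (rule in state$model$rules2) {
    if (rule$kind == "unnest" &&
        rule$species_a == state$species[row_inner] &&
        rule$species_b == state$species[row_shell]) return(TRUE)
  }
  FALSE
}

#' Particle accessors for rate and post-reaction functions
#'
#' Small helpers intended for use inside user-supplied rate, post-reaction and
#' split functions: read or write a single attribute (validated against the
#' schema), retarget a radius (the change is carried out continuously over
#' `growth_time`), or look up basic particle properties by id.
#'
#' @param state an `nf_state`.
#' @param id particle id.
#' @param name attribute name.
#' @param value new attribute value (must match the schema kind).
#' @param radius new target radius (m).
#' @export
p_attr <- function(state, id, name) state$attrs[[.nf_row(state, id)]][[name]]

#' @rdname p_attr
#' @export
p_set_attr <- function(state, id, name, value) {
  row <- .nf_row(state, id)
  sp <- state$model$species[[state$species[row]]]
  if (!name %in% names(sp$attributes))
    stop("attribute '", name, "' not in schema of '", sp$name, "'",
         call. = FALSE)
  if (.nf_kind_of(value) != sp$kinds[[name]])
    stop("attribute '", name, "' must be of kind ", sp$kinds[[name]],
         call. = FALSE)
  state$attrs[[row]][[name]] <- value
  invisible(state)
}

#' @rdname p_attr
#' @export
p_retarget_radius <- function(state, id, radius) {
  stopifnot(radius > 0)
  row <- .nf_row(state, id)
  state$target_radius[row] <- radius
  state$ramp_rate[row] <- abs(radius - state$radius[row]) /
    state$phys$growth_time
  invisible(state)
}

#' @rdname p_attr
#' @details `p_set_radius()` changes the radius immediately, without the
#'   continuous ramp. Safe for shrinking (losing volume creates no overlap,
#'   hence no artificial potential energy); growing a particle suddenly into
#'   neighbours is what [p_retarget_radius()] exists to avoid.
#' @export
p_set_radius <- function(state, id, radius) {
  stopifnot(radius > 0)
  row <- .nf_row(state, id)
  state$radius[row] <- radius
  state$target_radius[row] <- radius
  state$ramp_rate[row] <- 0
  invisible(state)
}

#' @rdname p_attr
#' @export
p_radius <- function(state, id) state$radius[.nf_row(state, id)]

#' @rdname p_attr
#' @export
p_position <- function(state, id) state$pos[.nf_row(state, id), ]

#' @rdname p_attr
#' @export
p_species <- function(state, id) state$species[.nf_row(state, id)]

#' @rdname p_attr
#' @export
p_parent <- function(state, id) state$parent[.nf_row(state, id)]

#' @rdname p_attr
#' @export
p_exists <- function(state, id) id %in% state$id
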