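#' Hertz contact: effective modulus and force law
#'
#' Soft-sphere excluded volume follows elastic contact theory: two overlapping
#' spheres repel with `F = (4/3) E* sqrt(r_eff d^3)` where `d` is the overlap
#' depth, `r_eff = (1/r1 + 1/r2)^-1` the effective radius and
#' `E* = ((1-nu1^2)/E1 + (1-nu2^2)/E2)^-1` the effective modulus composed from
#' the two Young's moduli and Poisson ratios. The force is zero at zero
#' overlap, continuous, and always pushes the spheres apart (for a particle
#' against its container's shell from inside: back toward the container
#' centre).
#'
#' @param E1,E2 Young's moduli (Pa), > 0.
#' @param nu1,nu2 Poisson ratios, in [0, 0.5).
#' @return effective modulus (Pa).
#' @export
effective_modulus <- function(E1, nu1, E2, nu2) {
  if (any(c(E1, E2) <= 0)) stop("Young's moduli must be > 0", call. = FALSE)
  1 / ((1 - nu1^2) / E1 + (1 - nu2^2) / E2)
}

#' @rdname effective_modulus
#' @param d overlap depth (m), >= 0; vectorised.
#' @param r1,r2 radii (m), > 0.
#' @param E_star effective modulus (Pa).
#' @param exponent contact-law exponent; 1.5 is Hertz, other positive values
#'   give a polynomial stiffness for sparse systems.
#' @return force magnitude (N).
#' @export
hertz_force <- function(d, r1, r2, E_star, exponent = 1.5) {
  if (any(d < 0)) stop("overlap depth must be >= 0", call. = FALSE)
  r_eff <- 1 / (1 / r1 + 1 / r2)
  (4 / 3) * E_star * sqrt(r_eff) * d^exponent
}

# cached per-species-pair effective modulus
.nf_pair_estar <- function(model, sa, sb) {
  key <- paste(sort(c(sa, sb)), collapse = "\r")
  hit <- model$estar_cache[[key]]
  if (!is.null(hit)) return(hit)
  A <- model$species[[sa]]
  B <- model$species[[sb]]
  v <- effective_modulus(A$young_modulus, A$poisson_ratio,
                         B$young_modulus, B$poisson_ratio)
  model$estar_cache[[key]] <- v
  v
}

#' Reactive force
#'
#' For a pair matching a bimolecular rule the non-reactive contact force is
#' replaced by a constant repulsive force `F = W / d_star` while the pair
#' overlaps, where `W` is the work required to cross the microscopic energy
#' barrier and `d_star` the required overlap for the reaction to trigger. The
#' work to push through the full required overlap is exactly
#' `F * d_star = W`; with `W = 0` (diffusion limited) the pair passes freely.
#'
#' @param W energy barrier (J), >= 0.
#' @param d_star required overlap (m), > 0.
#' @return force magnitude (N).
#' @export
reactive_force <- function(W, d_star) {
  if (any(d_star <= 0)) stop("d_star must be > 0", call. = FALSE)
  if (any(W < 0)) stop("W must be >= 0", call. = FALSE)
  W / d_star
}

#' Division force
#'
#' During compartment fission every particle of a moving half (the child shell
#' and all its contents) receives `F = m * a` along the division axis, each
#' with its own mass, so all members of a half share the same acceleration and
#' move uniformly.
#'
#' @param m mass (kg), > 0; vectorised.
#' @param a_division division acceleration (m/s^2), > 0.
#' @return force magnitude (N).
#' @export
division_force <- function(m, a_division) {
  if (any(m <= 0) || a_division <= 0)
    stop("mass and a_division must be > 0", call. = FALSE)
  m * a_division
}

#' Thermal (random) force
#'
#' The Gaussian random force of the Langevin equation. Its per-component
#' variance is fixed by the fluctuation-dissipation relation,
#' `sigma^2 = 2 gamma kB T / dt`, so that the equilibrium velocity variance is
#' `kB T / m` per component and the long-time mean squared displacement is
#' `2 d D t` with the Stokes-Einstein `D`.
#'
#' @param gamma friction coefficients (kg/s), vectorised over particles.
#' @param temperature temperature (K).
#' @param dt time step (s), > 0.
#' @param dimension 2 or 3.
#' @param kB Boltzmann constant (J/K).
#' @return an `n x dimension` matrix of forces (N).
#' @export
thermal_force <- function(gamma, temperature, dt, dimension = 3, kB = nf_kB) {
  stopifnot(dt > 0, temperature >= 0, all(gamma >= 0))
  n <- length(gamma)
  if (temperature == 0 || !n) return(matrix(0, n, dimension))
  sd <- sqrt(2 * gamma * kB * temperature / dt)
  matrix(stats::rnorm(n * dimension), n, dimension) * sd
}

#' Sum of external (global) force fields
#'
#' Evaluates every registered force field on the selected particles and
#' returns the vector sum. Pair forces and friction are not part of this term.
#' A field returning non-finite values aborts with a model error naming the
#' field.
#'
#' @param state an `nf_state`.
#' @param rows particle row indices (default: all).
#' @param t evaluation time (s).
#' @return an `length(rows) x dimension` force matrix (N).
#' @export
sum_external_forces <- function(state, rows = seq_len(state$n),
                                t = state$time) {
  f <- matrix(0, length(rows), state$dim)
  for (field in state$model$fields) {
    sel <- rep(TRUE, length(rows))
    if (!is.null(field$species))
      sel <- state$species[rows] %in% field$species
    if (!is.null(field$predicate) && any(sel))
      sel[sel] <- field$predicate(state, rows[sel])
    if (!any(sel)) next
    out <- field$fn(state, rows[sel], t)
    if (!all(is.finite(out)))
      stop("force field '", field$name, "' returned non-finite forces",
           call. = FALSE)
    f[sel, ] <- f[sel, ] + out
  }
  f
}

# division forces for all active transitions, as a full n x dim matrix
.nf_division_forces <- function(state) {
  f <- matrix(0, state$n, state$dim)
  for (tr in state$transitions) {
    for (side in 1:2) {
      cid <- tr$child_ids[side]
      row <- match(cid, state$id)
      if (is.na(row)) next
      members <- c(row, which(state$parent == cid))
      mm <- .nf_masses(state, members)
      dir <- if (side == 1L) tr$axis else -tr$axis
      f[members, ] <- f[members, ] +
        outer(division_force(mm, tr$a_division), dir)
    }
  }
  f
}
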