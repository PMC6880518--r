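# effective mobility: immobile species are anchored unless they take part in a
# division transition
.nf_mobility <- function(state) {
  if (!state$n) return(logical(0))
  state$mobile | state$in_transition
}

#' Adaptive time step
#'
#' `dt = r_min / (v_max * g)` with `r_min` the smallest current radius,
#' `v_max` the largest current speed among mobile particles and `g` the
#' granularity, clamped to `(0, max_timestep]`. With all velocities zero the
#' clamp value is returned. In explicit friction mode `v_max` is floored by
#' the thermal speed `sqrt(kB T / m)` of the lightest mobile particle (so cold
#' starts do not yield an infinite step) and the stability guard
#' `gamma dt / m <= 0.1` is enforced.
#'
#' @param state an `nf_state`.
#' @return time step (s).
#' @export
adaptive_timestep <- function(state) {
  p <- state$phys
  if (state$n == 0L) return(p$max_timestep)
  mob <- .nf_mobility(state)
  r_min <- min(state$radius)
  v_max <- if (any(mob)) max(sqrt(rowSums(state$vel[mob, , drop = FALSE]^2)))
           else 0
  if (p$friction_mode == "explicit" && any(mob)) {
    m <- .nf_masses(state)
    v_max <- max(v_max, sqrt(p$kB * p$temperature / min(m[mob])))
  }
  dt <- if (v_max > 0) r_min / (v_max * p$granularity) else p$max_timestep
  dt <- min(dt, p$max_timestep)
  if (p$friction_mode == "explicit" && any(mob)) {
    gam <- .nf_frictions(state)
    dt <- min(dt, 0.1 * min((.nf_masses(state) / gam)[mob]))
  }
  dt
}

#' Velocity and position updates (kick-drift-kick)
#'
#' `kick()` advances velocities by half a step under the total deterministic
#' force, friction and the thermal force; `drift()` advances positions by a
#' full step and applies the boundary. The same thermal force realisation is
#' used in both half-kicks of a step (drawn once, treated as constant over
#' `dt`). Friction enters either explicitly or in the unconditionally stable
#' semi-implicit form depending on `friction_mode`.
#'
#' @param state an `nf_state`.
#' @param f_det `n x dim` deterministic force matrix (pair + external +
#'   division forces), N.
#' @param f_thermal `n x dim` thermal force matrix, N.
#' @param dt_half half time step (s).
#' @export
kick <- function(state, f_det, f_thermal, dt_half) {
  if (!state$n) return(invisible(state))
  mob <- .nf_mobility(state)
  if (!any(mob)) return(invisible(state))
  # static system (no forces, no motion): velocities stay exactly zero
  if (!any(f_det != 0) && !any(f_thermal != 0) && !any(state$vel != 0))
    return(invisible(state))
  m <- .nf_masses(state)
  gam <- .nf_frictions(state)
  v <- state$vel
  ftot <- f_det + f_thermal
  if (state$phys$friction_mode == "explicit") {
    v <- v + (ftot - gam * v) * (dt_half / m)
  } else {
    v <- (v + ftot * (dt_half / m)) / (1 + gam * dt_half / m)
  }
  state$vel[mob, ] <- v[mob, , drop = FALSE]
  if (!all(is.finite(state$vel)))
    stop("numerical blow-up: non-finite velocities; increase granularity g ",
         "or reduce max_timestep", call. = FALSE)
  invisible(state)
}

#' @rdname kick
#' @param dt full time step (s).
#' @export
drift <- function(state, dt) {
  if (!state$n) return(invisible(state))
  mob <- .nf_mobility(state)
  if (!any(mob) || !any(state$vel[mob, ] != 0)) return(invisible(state))
  state$pos[mob, ] <- state$pos[mob, , drop = FALSE] +
    state$vel[mob, , drop = FALSE] * dt
  if (!all(is.finite(state$pos)))
    stop("numerical blow-up: non-finite positions; increase granularity g ",
         "or reduce max_timestep", call. = FALSE)
  boundary_apply(state)
}

#' Apply the domain boundary
#'
#' Called after every drift, for top-level particles only (contained particles
#' are confined by their shell, not the box). Reflective: mirror the position
#' and flip the normal velocity component. Absorbing: remove the particle and
#' its contents. Periodic: wrap into the box.
#'
#' @param state an `nf_state`.
#' @return the state, invisibly; absorbed ids are accumulated in
#'   `state$absorbed`.
#' @export
boundary_apply <- function(state) {
  if (!state$n) return(invisible(state))
  p <- state$phys
  top <- which(state$parent == 0L)
  if (!length(top)) return(invisible(state))
  x <- state$pos[top, , drop = FALSE]
  lo <- rep(p$domain_lo, each = length(top))
  hi <- rep(p$domain_hi, each = length(top))
  if (p$boundary == "periodic") {
    state$pos[top, ] <- lo + (x - lo) %% (hi - lo)
  } else if (p$boundary == "reflective") {
    v <- state$vel[top, , drop = FALSE]
    for (rep_i in 1:8) {        # repeated mirroring handles large overshoots
      below <- x < lo; above <- x > hi
      if (!any(below) && !any(above)) break
      x[below] <- 2 * lo[below] - x[below]
      x[above] <- 2 * hi[above] - x[above]
      v[below | above] <- -v[below | above]
    }
    state$pos[top, ] <- x
    state$vel[top, ] <- v
  } else { # absorbing
    out <- rowSums(x < lo | x > hi) > 0
    if (any(out)) {
      ids <- state$id[top[out]]
      state$absorbed <- c(state$absorbed, ids)
      remove_particles(state, ids)
    }
  }
  invisible(state)
}
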