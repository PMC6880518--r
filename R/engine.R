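.nf_hook <- function(state, phase) {
  if (!is.null(state$phase_hook)) state$phase_hook(phase)
  invisible(NULL)
}

#' Advance the simulation by one step
#'
#' Executes the canonical per-step sequence: (1) choose the adaptive time
#' step; (2) apply zeroth/first-order reactions, radius growth and division
#' progress; (3) evaluate deterministic forces (external fields, division
#' forces, pair forces carried over from the last collision phase — positions
#' have not changed since) plus one thermal force realisation, first half
#' kick, drift, boundary handling; (4) detect overlaps; (5) apply pair forces
#' (Hertz or reactive) and trigger bimolecular reactions; (6) second half kick
#' with the recomputed forces; (7) advance time and notify observers.
#'
#' @param state an `nf_state`.
#' @param observers list of observers (see [counts_observer()]).
#' @return the state, invisibly.
#' @export
step <- function(state, observers = NULL) {
  p <- state$phys
  dt <- adaptive_timestep(state)
  state$dt <- dt
  state$reacted <- rep(FALSE, state$n)

  .nf_hook(state, "lower_order")
  apply_lower_order(state, dt)

  .nf_hook(state, "integrate")
  ids0 <- state$id
  f_th <- thermal_force(.nf_frictions(state), p$temperature, dt, state$dim,
                        p$kB)
  f_det <- sum_external_forces(state) + .nf_division_forces(state) +
    state$pair_force
  kick(state, f_det, f_th, dt / 2)
  drift(state, dt)   # may absorb particles at the boundary

  .nf_hook(state, "collide")
  # with contact disabled and no bimolecular rules no pair can exert a force
  # or react, so the collision phases are vacuous and skipped
  inert <- !state$model$contact && !length(state$model$rules2)
  ov <- if (inert) structure(list(row_a = integer(0), row_b = integer(0),
                                  id_a = integer(0), id_b = integer(0),
                                  depth = numeric(0), distance = numeric(0),
                                  relation = character(0),
                                  normal = matrix(numeric(0), 0L, state$dim),
                                  n = 0L), class = "nf_overlaps")
        else detect_overlaps(state)

  .nf_hook(state, "bimolecular")
  pp <- .nf_pair_phase(state, ov)
  ids_pair <- state$id
  .nf_apply_events(state, pp$events)

  # realign per-particle force rows with the (possibly mutated) store
  state$pair_force <- .nf_realign(pp$force, ids_pair, state$id, state$dim)
  f_th <- .nf_realign(f_th, ids0, state$id, state$dim)

  .nf_hook(state, "second_kick")
  f_det2 <- sum_external_forces(state) + .nf_division_forces(state) +
    state$pair_force
  kick(state, f_det2, f_th, dt / 2)

  state$time <- state$time + dt
  state$nsteps <- state$nsteps + 1L
  .nf_hook(state, "observe")
  for (obs in observers) obs$record(state)
  invisible(state)
}

.nf_realign <- function(mat, old_ids, new_ids, dim) {
  if (identical(old_ids, new_ids)) return(mat)
  out <- matrix(0, length(new_ids), dim)
  map <- match(new_ids, old_ids)
  ok <- !is.na(map)
  out[ok, ] <- mat[map[ok], , drop = FALSE]
  out
}

#' Run a simulation
#'
#' `run_steps()` advances a fixed number of steps; `run_until()` advances
#' until the simulated time reaches `t_end`.
#'
#' @param state an `nf_state`.
#' @param n number of steps.
#' @param t_end end time (s).
#' @param observers list of observers; each is recorded at its own interval.
#' @return the state, invisibly.
#' @export
run_steps <- function(state, n, observers = NULL) {
  for (obs in observers) obs$start(state)
  for (i in seq_len(n)) step(state, observers)
  invisible(state)
}

#' @rdname run_steps
#' @export
run_until <- function(state, t_end, observers = NULL) {
  for (obs in observers) obs$start(state)
  while (state$time < t_end) step(state, observers)
  invisible(state)
}

#' Observers
#'
#' Observers receive a read-only view of the state after each step and must
#' not mutate it. `counts_observer()` records per-species particle counts
#' (split by compartment context: the species of the containing particle, or
#' `"medium"`); `trajectory_observer()` records full particle frames.
#' Recording happens at `t = 0` and then whenever the simulated time crosses
#' the next multiple of `interval` (or every `every` steps if given).
#'
#' @param interval recording interval in simulated seconds.
#' @param every alternatively, record every `every` steps.
#' @return an observer; query results with `$data()` (counts: a data.frame
#'   `time, species, count, compartment_context`; trajectory: a list of
#'   frames).
#' @export
counts_observer <- function(interval = NULL, every = NULL) {
  .nf_observer(interval, every, snap = function(state) {
    if (!state$n)
      return(data.frame(time = numeric(0), species = character(0),
                        count = integer(0),
                        compartment_context = character(0)))
    ctx <- ifelse(state$parent == 0L, "medium",
                  state$species[match(state$parent, state$id)])
    tab <- table(species = state$species, compartment_context = ctx)
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0, ]
    data.frame(time = state$time, species = df$species,
               count = as.integer(df$Freq),
               compartment_context = df$compartment_context)
  }, combine = function(frames) do.call(rbind, frames))
}

#' @rdname counts_observer
#' @export
trajectory_observer <- function(interval = NULL, every = NULL) {
  .nf_observer(interval, every, snap = function(state) {
    list(time = state$time, n = state$n, species = state$species,
         pos = state$pos, radius = state$radius, parent = state$parent,
         id = state$id)
  }, combine = identity)
}

.nf_observer <- function(interval, every, snap, combine) {
  if (is.null(interval) && is.null(every)) every <- 1L
  self <- new.env(parent = emptyenv())
  self$frames <- list()
  self$next_due <- 0
  self$start <- function(state) {
    if (!length(self$frames)) {
      self$frames[[1]] <- snap(state)
      self$next_due <- if (!is.null(interval)) interval else state$nsteps + every
    }
  }
  self$record <- function(state) {
    due <- if (!is.null(interval)) state$time >= self$next_due - 1e-12
           else state$nsteps >= self$next_due
    if (due) {
      self$frames[[length(self$frames) + 1L]] <- snap(state)
      if (!is.null(interval)) {
        while (self$next_due <= state$time + 1e-12)
          self$next_due <- self$next_due + interval
      } else self$next_due <- state$nsteps + every
    }
  }
  self$data <- function() combine(self$frames)
  class(self) <- "nf_observer"
  self
}
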