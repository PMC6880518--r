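# exact decimal round-trip for doubles (17 significant digits)
.nf_num2str <- function(x) sprintf("%.17g", x)
.nf_str2num <- function(s) as.numeric(s)

.nf_encode_attrs <- function(a) {
  lapply(a, function(v) {
    k <- .nf_kind_of(v)
    list(kind = k, value = if (k == "number") .nf_num2str(v)
                           else as.character(v))
  })
}

.nf_decode_attrs <- function(e) {
  lapply(e, function(v) {
    switch(v$kind[[1]],
           number = .nf_str2num(v$value[[1]]),
           integer = as.integer(v$value[[1]]),
           boolean = as.logical(v$value[[1]]),
           string = as.character(v$value[[1]]))
  })
}

#' Write species counts to CSV
#'
#' @param x a counts observer (see [counts_observer()]) or a data.frame with
#'   columns `time, species, count, compartment_context`.
#' @param path output file path.
#' @export
write_counts <- function(x, path) {
  df <- if (inherits(x, "nf_observer")) x$data() else x
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a trajectory in extended-XYZ text format
#'
#' One block per frame: the particle count, a comment line carrying the time,
#' then one line per particle: `species x y z radius parent_id` (2D runs write
#' z = 0). Human-readable and viewable in standard structure viewers.
#'
#' @param x a trajectory observer or its `$data()` frame list.
#' @param path output file path.
#' @export
write_trajectory <- function(x, path) {
  frames <- if (inherits(x, "nf_observer")) x$data() else x
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(c(as.character(fr$n),
                 sprintf("time=%s", .nf_num2str(fr$time))), con)
    if (fr$n) {
      pos3 <- fr$pos
      if (ncol(pos3) == 2L) pos3 <- cbind(pos3, 0)
      writeLines(sprintf("%s %s %s %s %s %d", fr$species,
                         .nf_num2str(pos3[, 1]), .nf_num2str(pos3[, 2]),
                         .nf_num2str(pos3[, 3]), .nf_num2str(fr$radius),
                         fr$parent), con)
    }
  }
  invisible(path)
}

#' Snapshot serialization
#'
#' Writes the full simulation state — particle store, attributes, containment
#' links, ignore sets, active transitions, physics parameters and the RNG
#' state — as JSON. All doubles are encoded with 17 significant digits, so a
#' snapshot round-trips losslessly: loading a snapshot and continuing a run
#' gives bit-identical trajectories to the uninterrupted run, and
#' write-load-write is byte-idempotent.
#'
#' @param state an `nf_state`.
#' @param path file path.
#' @export
write_snapshot <- function(state, path) {
  num <- .nf_num2str
  mat <- function(m) lapply(seq_len(nrow(m)), function(i) num(m[i, ]))
  p <- state$phys
  obj <- list(
    format = "nestforce-snapshot-1",
    dim = state$dim, time = num(state$time), nsteps = state$nsteps,
    next_id = state$next_id, seed = state$seed,
    rng = get(".Random.seed", envir = globalenv()),
    physics = list(temperature = num(p$temperature),
                   viscosity = num(p$viscosity),
                   granularity = num(p$granularity),
                   max_timestep = num(p$max_timestep),
                   domain_lo = num(p$domain_lo), domain_hi = num(p$domain_hi),
                   boundary = p$boundary, tol_contain = num(p$tol_contain),
                   growth_time = num(p$growth_time),
                   friction_mode = p$friction_mode, kB = num(p$kB)),
    particles = list(
      id = state$id, species = state$species, pos = mat(state$pos),
      vel = mat(state$vel), radius = num(state$radius),
      target_radius = num(state$target_radius),
      ramp_rate = num(state$ramp_rate), density = num(state$density),
      parent = state$parent,
      in_transition = state$in_transition,
      ignore = state$ignore,
      attrs = lapply(state$attrs, .nf_encode_attrs)),
    pair_force = mat(state$pair_force),
    transitions = lapply(state$transitions, function(tr)
      list(kind = tr$kind, child_ids = tr$child_ids, axis = num(tr$axis),
           a_division = num(tr$a_division), r_start = num(tr$r_start),
           r_targets = num(tr$r_targets), start_time = num(tr$start_time),
           steps = tr$steps)),
    absorbed = as.integer(state$absorbed %||% integer(0)))
  writeLines(jsonlite::toJSON(obj, auto_unbox = FALSE, pretty = FALSE,
                              digits = NA), path)
  invisible(path)
}

#' @rdname write_snapshot
#' @param model the `nf_model` the snapshot was taken from (rate, post and
#'   force functions are code and are not serialized).
#' @return `load_snapshot()`: a restored `nf_state`.
#' @export
load_snapshot <- function(model, path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$format[[1]], "nestforce-snapshot-1"))
    stop("not a nestforce snapshot: ", path, call. = FALSE)
  num1 <- function(x) .nf_str2num(x[[1]])
  numv <- function(x) vapply(x, .nf_str2num, numeric(1))
  ph <- obj$physics
  phys <- physics_params(
    temperature = num1(ph$temperature), viscosity = num1(ph$viscosity),
    granularity = num1(ph$granularity), max_timestep = num1(ph$max_timestep),
    domain_lo = numv(ph$domain_lo), domain_hi = numv(ph$domain_hi),
    boundary = ph$boundary[[1]], tol_contain = num1(ph$tol_contain),
    growth_time = num1(ph$growth_time), friction_mode = ph$friction_mode[[1]],
    kB = num1(ph$kB))
  st <- new_state(model, phys, seed = obj$seed[[1]])
  dim <- obj$dim[[1]]
  if (dim != model$dimension)
    stop("snapshot dimension does not match the model", call. = FALSE)
  pp <- obj$particles
  n <- length(pp$id)
  st$time <- num1(obj$time)
  st$nsteps <- as.integer(obj$nsteps[[1]])
  st$next_id <- as.integer(obj$next_id[[1]])
  st$n <- n
  st$id <- vapply(pp$id, as.integer, integer(1))
  st$species <- vapply(pp$species, as.character, character(1))
  tomat <- function(rows) {
    if (!length(rows)) return(matrix(numeric(0), 0L, dim))
    do.call(rbind, lapply(rows, numv))
  }
  st$pos <- tomat(pp$pos)
  st$vel <- tomat(pp$vel)
  st$radius <- numv(pp$radius)
  st$target_radius <- numv(pp$target_radius)
  st$ramp_rate <- numv(pp$ramp_rate)
  st$density <- numv(pp$density)
  st$parent <- vapply(pp$parent, as.integer, integer(1))
  st$in_transition <- vapply(pp$in_transition, as.logical, logical(1))
  st$ignore <- lapply(pp$ignore, function(v)
    if (length(v)) vapply(v, as.integer, integer(1)) else integer(0))
  st$attrs <- lapply(pp$attrs, .nf_decode_attrs)
  st$reacted <- rep(FALSE, n)
  st$mobile <- vapply(st$species,
                      function(s) model$species[[s]]$mobile, logical(1),
                      USE.NAMES = FALSE)
  st$pair_force <- tomat(obj$pair_force)
  st$transitions <- lapply(obj$transitions, function(tr)
    list(kind = tr$kind[[1]],
         child_ids = vapply(tr$child_ids, as.integer, integer(1)),
         axis = numv(tr$axis), a_division = num1(tr$a_division),
         r_start = num1(tr$r_start), r_targets = numv(tr$r_targets),
         start_time = num1(tr$start_time), steps = as.integer(tr$steps[[1]])))
  st$absorbed <- if (length(obj$absorbed))
    vapply(obj$absorbed, as.integer, integer(1)) else NULL
  assign(".Random.seed", vapply(obj$rng, as.integer, integer(1)),
         envir = globalenv())
  st
}
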