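#' Stochastic firing test
#'
#' A rule with propensity `rate` fires within a step of length `dt` with
#' probability `1 - exp(-rate * dt)` — identical to `rate * dt` to first order
#' but never exceeding one, so arbitrarily large propensities remain valid. At
#' most one reaction per particle fires per step.
#'
#' @param rate propensity (1/s), vectorised; must be >= 0.
#' @param dt time step (s).
#' @return logical vector of firing decisions (consumes one uniform draw per
#'   entry).
#' @export
should_fire <- function(rate, dt) {
  if (any(rate < 0)) stop("negative propensity", call. = FALSE)
  stopifnot(dt > 0)
  stats::runif(length(rate)) < 1 - exp(-rate * dt)
}

#' Continuous radius ramp
#'
#' Moves every particle's radius toward its target at the constant rate fixed
#' when the ramp started (|target - start| / growth_time), clamped at the
#' target. Applies to creation reactions, explicit radius-change reactions and
#' budding; radii of compartments in fission are interpolated by the division
#' transition instead and are skipped here.
#'
#' @param state an `nf_state`.
#' @param dt time step (s).
#' @export
grow_step <- function(state, dt) {
  act <- which(state$radius != state$target_radius & !state$in_transition &
               state$ramp_rate > 0)
  if (!length(act)) return(invisible(state))
  dr <- state$ramp_rate[act] * dt
  gap <- state$target_radius[act] - state$radius[act]
  step <- sign(gap) * pmin(abs(gap), dr)
  state$radius[act] <- state$radius[act] + step
  invisible(state)
}

.nf_rule_rates <- function(state, rule, rows) {
  if (is.numeric(rule$rate)) return(rep(rule$rate, length(rows)))
  r <- vapply(state$id[rows], function(id) rule$rate(state, id), numeric(1))
  if (any(r < 0))
    stop("rate function of rule on '",
         rule$species %||% rule$product, "' returned a negative propensity",
         call. = FALSE)
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# uniform point in the unit ball (dim 2 or 3)
.nf_runif_ball <- function(dim) {
  u <- stats::rnorm(dim)
  u <- u / sqrt(sum(u^2))
  u * stats::runif(1)^(1 / dim)
}

.nf_runif_dir <- function(dim) {
  u <- stats::rnorm(dim)
  u / sqrt(sum(u^2))
}

.nf_spawn_order0 <- function(state, rule) {
  sp <- state$model$species[[rule$product]]
  r_tgt <- rule$radius %||% sp$radius
  if (rule$placement == "random_in_domain") {
    pos <- stats::runif(state$dim, state$phys$domain_lo, state$phys$domain_hi)
    spawn_particle(state, rule$product, pos, parent = 0L, radius = rule$radius,
                   attrs = rule$attrs, grown = FALSE)
  } else {
    hosts <- which(state$species == rule$parent_species)
    if (!length(hosts)) return(invisible(NULL))
    h <- hosts[sample.int(length(hosts), 1L)]
    if (rule$placement == "inside") {
      room <- state$radius[h] - r_tgt
      if (room <= 0) {
        warning("order-0 product does not fit inside any '",
                rule$parent_species, "'; skipped", call. = FALSE)
        return(invisible(NULL))
      }
      pos <- state$pos[h, ] + .nf_runif_ball(state$dim) * room
      spawn_particle(state, rule$product, pos, parent = state$id[h],
                     radius = rule$radius, attrs = rule$attrs, grown = FALSE)
    } else { # surface: the new shell barely touches the host's shell, outside
      r0 <- r_tgt / 100
      pos <- state$pos[h, ] + .nf_runif_dir(state$dim) * (state$radius[h] + r0)
      spawn_particle(state, rule$product, pos, parent = state$parent[h],
                     radius = rule$radius, attrs = rule$attrs, grown = FALSE,
                     check_fit = FALSE)
    }
  }
}

#' Apply zeroth- and first-order reactions
#'
#' Runs at the start of every engine step. Zeroth-order rules draw their event
#' count from Poisson(rate * dt) (exact for any step size) and place each
#' product per the rule's placement. First-order rules (including division
#' rules) evaluate their propensity per matching particle that has not yet
#' reacted this step, test [should_fire()], and on success run the
#' post-reaction function or start the division transition; at most one
#' reaction per particle per step. Radius ramps and division progress
#' bookkeeping run here as well.
#'
#' @param state an `nf_state`.
#' @param dt time step (s).
#' @return the state, invisibly.
#' @export
apply_lower_order <- function(state, dt) {
  grow_step(state, dt)
  .nf_progress_divisions(state, dt)
  for (rule in state$model$rules0) {
    rate <- if (is.numeric(rule$rate)) rule$rate else rule$rate(state)
    if (rate < 0) stop("negative zeroth-order rate for product '",
                       rule$product, "'", call. = FALSE)
    k <- stats::rpois(1L, rate * dt)
    for (i in seq_len(k)) .nf_spawn_order0(state, rule)
  }
  for (rule in state$model$rules1) {
    rows <- which(state$species == rule$species & !state$reacted &
                  !state$in_transition)
    if (!length(rows)) next
    if (!is.null(rule$predicate)) {
      ok <- vapply(state$id[rows], function(id) rule$predicate(state, id),
                   logical(1))
      rows <- rows[ok]
      if (!length(rows)) next
    }
    rates <- .nf_rule_rates(state, rule, rows)
    fire <- should_fire(rates, dt)
    if (!any(fire)) next
    for (id in state$id[rows[fire]]) {
      row <- match(id, state$id)
      if (is.na(row) || state$reacted[row] || state$in_transition[row]) next
      state$reacted[row] <- TRUE
      if (rule$kind == "divide") start_division(state, id, rule)
      else rule$post(state, id)
    }
  }
  invisible(state)
}

#' Start a compartment division
#'
#' Replaces the dividing particle by two children at its position (offset by a
#' tiny epsilon along a uniformly random axis), both at the parent's radius.
#' Each content particle is assigned to one child (independent fair coin by
#' default, or the rule's split function), and ignore relations are installed:
#' the children ignore each other, and each content ignores the opposite
#' child's shell. The children's radii interpolate from the start radius to
#' their targets as the halves separate under the division force; on
#' completion (fully outside one another) all ignore relations are removed.
#'
#' @param state an `nf_state`.
#' @param id id of the dividing particle.
#' @param rule an `nf_rule1` of kind `"divide"`.
#' @return the transition record, invisibly.
#' @export
start_division <- function(state, id, rule) {
  row <- .nf_row(state, id)
  sp_name <- state$species[row]
  pos0 <- state$pos[row, ]
  vel0 <- state$vel[row, ]
  r0 <- state$radius[row]
  grandparent <- state$parent[row]
  content <- children(state, id)
  axis <- .nf_runif_dir(state$dim)
  eps <- r0 * 1e-6

  r_targets <- r0 * rule$radius_fractions
  attr_overrides <- list(
    if (is.null(rule$attrs1)) list() else rule$attrs1(state, id),
    if (is.null(rule$attrs2)) list() else rule$attrs2(state, id))
  base_attrs <- state$attrs[[row]]

  assign12 <- if (length(content)) {
    a <- if (is.null(rule$split)) 1L + stats::rbinom(length(content), 1L, 0.5)
         else as.integer(rule$split(state, id, content))
    stopifnot(length(a) == length(content), all(a %in% 1:2))
    a
  } else integer(0)

  child_ids <- integer(2)
  for (side in 1:2) {
    a <- base_attrs
    for (nm in names(attr_overrides[[side]]))
      a[[nm]] <- attr_overrides[[side]][[nm]]
    cid <- spawn_particle(state, sp_name,
                          pos0 + (if (side == 1L) eps else -eps) * axis,
                          parent = grandparent, radius = r0, attrs = a,
                          velocity = vel0, grown = TRUE, check_fit = FALSE)
    child_ids[side] <- cid
  }
  # content reassignment and ignore relations
  for (k in seq_along(content)) {
    crow <- match(content[k], state$id)
    keep <- child_ids[assign12[k]]
    other <- child_ids[3L - assign12[k]]
    if (state$radius[crow] > min(r_targets))
      warning("division content ", content[k],
              " may not fit the smaller child at completion", call. = FALSE)
    state$parent[crow] <- keep
    state$ignore[[crow]] <- c(state$ignore[[crow]], other)
    state$in_transition[crow] <- TRUE
  }
  c1 <- match(child_ids[1], state$id); c2 <- match(child_ids[2], state$id)
  state$ignore[[c1]] <- c(state$ignore[[c1]], child_ids[2])
  state$ignore[[c2]] <- c(state$ignore[[c2]], child_ids[1])
  state$in_transition[c(c1, c2)] <- TRUE
  state$target_radius[c(c1, c2)] <- r_targets
  remove_particles(state, id)

  tr <- list(kind = "division", child_ids = child_ids, axis = axis,
             a_division = rule$a_division, r_start = r0,
             r_targets = r_targets, start_time = state$time, steps = 0L)
  state$transitions <- c(state$transitions, list(tr))
  invisible(tr)
}

# advance all division transitions: radius interpolation r(s) with progress
# s = separation / (r_t1 + r_t2), completion when fully outside one another
.nf_progress_divisions <- function(state, dt) {
  if (!length(state$transitions)) return(invisible(state))
  done <- logical(length(state$transitions))
  for (ti in seq_along(state$transitions)) {
    tr <- state$transitions[[ti]]
    c1 <- match(tr$child_ids[1], state$id)
    c2 <- match(tr$child_ids[2], state$id)
    if (is.na(c1) || is.na(c2)) { done[ti] <- TRUE; next }
    dvec <- .nf_pair_diff(state, state$pos[c1, , drop = FALSE],
                          state$pos[c2, , drop = FALSE],
                          top = state$parent[c1] == 0L)
    sep <- sqrt(sum(dvec^2))
    s <- min(sep / sum(tr$r_targets), 1)
    state$radius[c(c1, c2)] <- tr$r_start + s * (tr$r_targets - tr$r_start)
    tr$steps <- tr$steps + 1L
    if (tr$steps == 200000L)
      warning("division of children ", paste(tr$child_ids, collapse = "/"),
              " has not completed after 2e5 steps; a_division may be too ",
              "small for the local friction", call. = FALSE)
    state$transitions[[ti]] <- tr
    if (sep >= sum(state$radius[c(c1, c2)])) {
      .nf_complete_division(state, tr, c1, c2)
      done[ti] <- TRUE
    }
  }
  if (any(done)) state$transitions <- state$transitions[!done]
  invisible(state)
}

.nf_complete_division <- function(state, tr, c1, c2) {
  state$radius[c(c1, c2)] <- tr$r_targets
  members <- c(c1, c2,
               which(state$parent %in% tr$child_ids))
  for (m in members) state$ignore[[m]] <- integer(0)
  state$in_transition[members] <- FALSE
  invisible(state)
}

# --- bimolecular machinery ---------------------------------------------------

.nf_resolve_dstar <- function(rule, r_a, r_b) {
  if (!is.null(rule$d_star)) rule$d_star
  else rule$d_star_frac * min(r_a, r_b)
}

.nf_context_ok <- function(state, rule, row_a) {
  if (is.null(rule$context)) return(TRUE)
  p <- state$parent[row_a]
  if (identical(rule$context, "top")) return(p == 0L)
  p != 0L && state$species[match(p, state$id)] == rule$context
}

# find the bimolecular rule matching an overlap pair; returns NULL or
# list(rule, inner_row, shell_row) with orientation resolved
.nf_match_rule2 <- function(state, row_a, row_b, relation) {
  sa <- state$species[row_a]; sb <- state$species[row_b]
  ok <- function(rule, a, b) {
    is.null(rule$predicate) ||
      rule$predicate(state, state$id[a], state$id[b])
  }
  for (rule in state$model$rules2) {
    if (relation == "inner_shell") {
      if (rule$kind == "unnest" && sa == rule$species_a &&
          sb == rule$species_b && ok(rule, row_a, row_b))
        return(list(rule = rule, a = row_a, b = row_b))
    } else if (relation == "free_free") {
      if (rule$kind %in% c("fuse", "transform", "nest")) {
        if (sa == rule$species_a && sb == rule$species_b &&
            .nf_context_ok(state, rule, row_a) && ok(rule, row_a, row_b))
          return(list(rule = rule, a = row_a, b = row_b))
        if (sb == rule$species_a && sa == rule$species_b &&
            .nf_context_ok(state, rule, row_b) && ok(rule, row_b, row_a))
          return(list(rule = rule, a = row_b, b = row_a))
      }
    }
  }
  NULL
}

# pair forces (Hertz or reactive) and bimolecular trigger candidates for all
# detected overlaps; returns list(force = n x dim matrix, events = list).
# Non-reactive contacts are handled on a fully vectorised path; reactive pairs
# (those matching a bimolecular rule with both members unreacted) are few and
# handled individually.
.nf_pair_phase <- function(state, ov) {
  n <- state$n
  f <- matrix(0, n, state$dim)
  events <- list()
  if (!ov$n) return(list(force = f, events = events))
  model <- state$model

  reactive <- rep(FALSE, ov$n)
  if (length(model$rules2)) {
    can <- !state$reacted[ov$row_a] & !state$reacted[ov$row_b]
    for (k in which(can)) {
      m2 <- .nf_match_rule2(state, ov$row_a[k], ov$row_b[k], ov$relation[k])
      if (is.null(m2)) next
      reactive[k] <- TRUE
      rule <- m2$rule
      ds <- .nf_resolve_dstar(rule, state$radius[m2$a], state$radius[m2$b])
      Fm <- reactive_force(rule$W, ds)
      trig <- switch(rule$kind,
        fuse = ,
        transform = ov$depth[k] > ds,
        nest = ov$distance[k] + state$radius[m2$a] <=
                 state$radius[m2$b] + state$phys$tol_contain,
        unnest = ov$distance[k] >=
                 state$radius[m2$a] + state$radius[m2$b])
      if (trig)
        events[[length(events) + 1L]] <-
          list(kind = rule$kind, rule = rule,
               id_a = state$id[m2$a], id_b = state$id[m2$b])
      if (Fm != 0) {  # normal is oriented on ov$row_a regardless of the
        fv <- Fm * ov$normal[k, ]  # rule's reactant orientation
        f[ov$row_a[k], ] <- f[ov$row_a[k], ] + fv
        f[ov$row_b[k], ] <- f[ov$row_b[k], ] - fv
      }
    }
  }

  plain <- which(!reactive)
  if (model$contact && length(plain)) {
    ra <- ov$row_a[plain]; rb <- ov$row_b[plain]
    spa <- state$species[ra]; spb <- state$species[rb]
    key <- paste(pmin(spa, spb), pmax(spa, spb))
    uk <- unique(key)
    es <- vapply(strsplit(uk, " ", fixed = TRUE), function(p)
      .nf_pair_estar(model, p[1], p[2]), numeric(1))
    estar <- es[match(key, uk)]
    Fm <- hertz_force(ov$depth[plain], state$radius[ra], state$radius[rb],
                      estar, model$stiffness_exponent)
    fv <- Fm * ov$normal[plain, , drop = FALSE]
    idx <- c(ra, rb)
    agg <- rowsum(rbind(fv, -fv), idx)
    rows <- as.integer(rownames(agg))
    f[rows, ] <- f[rows, ] + agg
  }
  list(force = f, events = events)
}

# resolve simultaneous trigger candidates: uniform random order, one reaction
# per particle per step
.nf_apply_events <- function(state, events) {
  if (!length(events)) return(invisible(state))
  ord <- if (length(events) > 1L) sample.int(length(events)) else 1L
  for (e in events[ord]) {
    ra <- match(e$id_a, state$id); rb <- match(e$id_b, state$id)
    if (is.na(ra) || is.na(rb)) next
    if (state$reacted[ra] || state$reacted[rb]) next
    switch(e$kind,
      fuse = apply_fusion(state, e$id_a, e$id_b, e$rule),
      transform = {
        state$reacted[c(ra, rb)] <- TRUE
        e$rule$post(state, e$id_a, e$id_b)
      },
      nest = {
        state$reacted[c(ra, rb)] <- TRUE
        reparent(state, e$id_a, e$id_b)
        if (!is.null(e$rule$post)) e$rule$post(state, e$id_a, e$id_b)
      },
      unnest = {
        state$reacted[c(ra, rb)] <- TRUE
        reparent(state, e$id_a, state$parent[rb])
        if (!is.null(e$rule$post)) e$rule$post(state, e$id_a, e$id_b)
      })
  }
  invisible(state)
}

#' Fuse two particles
#'
#' The product is placed at the mass-weighted centroid with
#' momentum-conserving velocity; its radius conserves total volume
#' (`r^3 = r_a^3 + r_b^3` in 3D, area in 2D) unless the post-reaction function
#' retargets it. The contents of both reactants are merged into the product.
#' The rule's post function, if any, is called as
#' `post(state, product_id, attrs_a, attrs_b)` and may rewrite product
#' attributes (e.g. transfer SNARE counters on vesicle fusion). A product
#' transiently breaching its parent's shell is placed anyway and resolved by
#' contact forces.
#'
#' @param state an `nf_state`.
#' @param id_a,id_b reactant ids (siblings).
#' @param rule the matched fuse rule.
#' @return the product particle id.
#' @export
apply_fusion <- function(state, id_a, id_b, rule) {
  ra <- .nf_row(state, id_a); rb <- .nf_row(state, id_b)
  ma <- .nf_masses(state, ra); mb <- .nf_masses(state, rb)
  if (xor(state$mobile[ra], state$mobile[rb])) {
    # one reactant is spatially anchored: the product inherits its position
    anchor <- if (state$mobile[ra]) rb else ra
    pos <- state$pos[anchor, ]
    vel <- state$vel[anchor, ]
  } else {
    pos <- (ma * state$pos[ra, ] + mb * state$pos[rb, ]) / (ma + mb)
    vel <- (ma * state$vel[ra, ] + mb * state$vel[rb, ]) / (ma + mb)
  }
  r_new <- if (state$dim == 3L)
    (state$radius[ra]^3 + state$radius[rb]^3)^(1 / 3)
  else sqrt(state$radius[ra]^2 + state$radius[rb]^2)
  parent <- state$parent[ra]
  attrs_a <- state$attrs[[ra]]; attrs_b <- state$attrs[[rb]]
  content <- c(children(state, id_a), children(state, id_b))
  pid <- spawn_particle(state, rule$product, pos, parent = parent,
                        radius = r_new, velocity = vel, grown = TRUE,
                        check_fit = FALSE)
  for (cid in content) state$parent[match(cid, state$id)] <- pid
  remove_particles(state, c(id_a, id_b))
  if (!is.null(rule$post)) rule$post(state, pid, attrs_a, attrs_b)
  pid
}
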