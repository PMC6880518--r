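#' Vesicular-transport scenario
#'
#' Two membrane compartments inside a cell of radius 2.5 um exchange SNARE
#' receptors via budding and fusing vesicles. In the directed variant the
#' first compartment starts nine times bigger (V1 ~ 0.118 um^3 vs
#' V2 ~ 0.013 um^3) and holds 90% of the SNAREs (90000 + 10000 per type at
#' scale 1), and a dipole-like force field pulls X-coated vesicles to
#' compartment 1 and Y-coated vesicles to compartment 2 (abstracting
#' motor-protein transport). The control variant starts with equal
#' compartments (V ~ 0.065 um^3, 50000 + 50000 SNAREs per type) and no field.
#' Budding is a first-order rule whose rate is linear in compartment volume;
#' each vesicle carries a SNARE packet enriched (80%) in its coat type and the
#' compartment radius is retargeted to conserve volume; fusion transfers the
#' packet and the volume back. Compartments and the cell are spatially
#' anchored.
#'
#' @param seed RNG seed.
#' @param directed logical; `FALSE` gives the pure-Brownian control.
#' @param scale count scale factor in (0, 1]: SNARE counts are multiplied by
#'   `scale` (desk-scale fixtures use ~0.01; geometry is unscaled).
#' @param k_bud budding rate constant (1/s per vesicle-volume of compartment
#'   volume).
#' @param field_strength dipole force magnitude (N) on vesicles.
#' @param t_step engine step bound (s).
#' @return list with the state and the ids of cell and compartments.
#' @export
scenario_vesicle <- function(seed = 1L, directed = TRUE, scale = 1,
                             k_bud = 40, field_strength = 6e-13,
                             t_step = 5e-6) {
  stopifnot(scale > 0, scale <= 1)
  n_big <- round(90000 * scale); n_small <- round(10000 * scale)
  n_half <- round(50000 * scale)
  if ((directed && n_small < 1) || (!directed && n_half < 1))
    stop("scale so small that SNARE counts round to zero", call. = FALSE)
  r_ves <- 5e-8
  v_ves <- (4 / 3) * pi * r_ves^3
  r1 <- if (directed) (3 * 0.118e-18 / (4 * pi))^(1 / 3)
        else (3 * 0.065e-18 / (4 * pi))^(1 / 3)
  r2 <- if (directed) (3 * 0.013e-18 / (4 * pi))^(1 / 3) else r1

  m <- new_model(3, contact = TRUE)
  register_species(m, "Cell", radius = 2.5e-6, density = 1000, mobile = FALSE)
  register_species(m, "Comp", radius = r1, density = 1000, mobile = FALSE,
                   attributes = list(snareX = 0, snareY = 0, tag = 0L))
  register_species(m, "Ves", radius = r_ves, density = 1000,
                   attributes = list(coat = "X", snareX = 0, snareY = 0))

  bud_rate <- function(state, id) {
    v <- (4 / 3) * pi * p_radius(state, id)^3
    if (v < 8 * v_ves) 0 else k_bud * v / v_ves
  }
  bud_post <- function(state, id) {
    sx <- p_attr(state, id, "snareX"); sy <- p_attr(state, id, "snareY")
    tot <- sx + sy
    if (tot < 1) return(invisible(NULL))
    coat <- if (stats::runif(1) < sx / tot) "X" else "Y"
    r_c <- p_radius(state, id)
    n_pack <- max(1, round(tot * v_ves / ((4 / 3) * pi * r_c^3)))
    n_coat <- min(round(0.8 * n_pack), if (coat == "X") sx else sy)
    n_oth <- min(n_pack - n_coat, if (coat == "X") sy else sx)
    vx <- if (coat == "X") n_coat else n_oth
    vy <- if (coat == "X") n_oth else n_coat
    dir <- .nf_runif_dir(3)
    vid <- spawn_particle(state, "Ves",
                          p_position(state, id) + dir * (r_c + 1.05 * r_ves),
                          parent = p_parent(state, id),
                          attrs = list(coat = coat, snareX = vx, snareY = vy),
                          grown = TRUE, check_fit = FALSE)
    p_set_attr(state, id, "snareX", sx - vx)
    p_set_attr(state, id, "snareY", sy - vy)
    # immediate shrink: exact volume bookkeeping even when buds overlap in time
    p_set_radius(state, id, (r_c^3 - r_ves^3)^(1 / 3))
    invisible(vid)
  }
  add_rule(m, rule_first("Comp", rate = bud_rate, post = bud_post))
  add_rule(m, rule_bimolecular("Ves", "Comp", kind = "fuse", product = "Comp",
                               d_star_frac = 0.2, W = 0,
    post = function(state, pid, attrs_ves, attrs_comp) {
      p_set_attr(state, pid, "snareX", attrs_comp$snareX + attrs_ves$snareX)
      p_set_attr(state, pid, "snareY", attrs_comp$snareY + attrs_ves$snareY)
      p_set_attr(state, pid, "tag", attrs_comp$tag)
    }))

  ctr <- rep(3e-6, 3)
  pole1 <- ctr + c(-1e-6, 0, 0); pole2 <- ctr + c(1e-6, 0, 0)
  if (directed)
    add_field(m, dipole_field("motors", pole1, pole2, field_strength, "Ves",
                              selector = function(a)
                                if (a$coat == "X") 1L else 2L))

  ph <- physics_params(temperature = 310, viscosity = 1e-3,
                       max_timestep = t_step, granularity = 1,
                       domain_lo = rep(0, 3), domain_hi = rep(6e-6, 3),
                       friction_mode = "semi_implicit", growth_time = 1e-4,
                       tol_contain = 1e-9)
  st <- new_state(m, ph, seed)
  cell <- spawn_particle(st, "Cell", ctr)
  cx <- if (directed) c(n_big, n_small) else c(n_half, n_half)
  c1 <- spawn_particle(st, "Comp", pole1, parent = cell, radius = r1,
                       attrs = list(snareX = cx[1], snareY = cx[1],
                                    tag = 1L))
  c2 <- spawn_particle(st, "Comp", pole2, parent = cell, radius = r2,
                       attrs = list(snareX = cx[2], snareY = cx[2],
                                    tag = 2L))
  list(state = st, cell = cell, comps = c(c1, c2))
}

#' Vesicle-scenario summary metrics
#'
#' Compartment volumes (by tag), the relative volume asymmetry
#' |V1 - V2| / (V1 + V2), the SNARE-X fraction in compartment 1 and the
#' system-wide totals of each SNARE type (compartments plus vesicles in
#' flight), used by the validation suite.
#'
#' @param state a vesicle-scenario state.
#' @return a named list.
#' @export
vesicle_metrics <- function(state) {
  comp <- which(state$species == "Comp")
  tag <- vapply(comp, function(r) as.integer(state$attrs[[r]]$tag),
                integer(1))
  vol <- (4 / 3) * pi * state$radius[comp]^3
  v1 <- sum(vol[tag == 1L]); v2 <- sum(vol[tag == 2L])
  c1 <- comp[tag == 1L][1]
  sx1 <- state$attrs[[c1]]$snareX; sy1 <- state$attrs[[c1]]$snareY
  allx <- sum(vapply(which(state$species %in% c("Comp", "Ves")),
                     function(r) state$attrs[[r]]$snareX, numeric(1)))
  ally <- sum(vapply(which(state$species %in% c("Comp", "Ves")),
                     function(r) state$attrs[[r]]$snareY, numeric(1)))
  list(v1 = v1, v2 = v2, asymmetry = abs(v1 - v2) / (v1 + v2),
       fracX1 = if (sx1 + sy1 > 0) sx1 / (sx1 + sy1) else NA_real_,
       totalX = allx, totalY = ally,
       n_vesicles = sum(state$species == "Ves"))
}

#' Yeast colony scenario
#'
#' 2D fission-yeast toy model. Cells are immobile particles whose cell cycle
#' is a non-spatial attribute oscillator: a first-order rule increments the
#' cycle variable `cycM` in steps of 0.01 at a base rate of 100 increments per
#' 120-minute period, slowed by a factor 1/(1 + bound/K) by bound pheromone;
#' when `cycM` reaches 1 the cell divides (children reset the cycle, the
#' second child re-draws its mating type). Cells of mating type P emit
#' P-factor, M cells emit M-factor and the protease Sxa2; pheromones diffuse
#' in the medium, are absorbed at the domain border, bind cells of the
#' opposite type (incrementing `bound`), and Sxa2 annihilates P-factor.
#'
#' @param seed RNG seed.
#' @param n_cells initial cell count (alternating mating types on a lattice).
#' @param k_emit pheromone emission rate per cell (1/s); 0 disables emission
#'   (useful to study the bare oscillator at large time steps).
#' @param k_inh inhibition constant K (bound pheromones halving the cycle
#'   rate).
#' @param period unbound cell-cycle period (s); default 120 min.
#' @param t_step engine step bound (s).
#' @return list with the state and initial cell ids.
#' @export
scenario_yeast <- function(seed = 1L, n_cells = 4L, k_emit = 0.5,
                           k_inh = 50, period = 120 * 60, t_step = 1e-6) {
  m <- new_model(2, contact = TRUE)
  register_species(m, "Cell", radius = 2e-6, density = 1000, mobile = FALSE,
                   attributes = list(mating = "P", cycM = 0, bound = 0))
  for (s in c("Pfac", "Mfac", "Sxa2"))
    register_species(m, s, radius = 2e-8, density = 1000)

  cyc_rate <- function(state, id)
    (100 / period) / (1 + p_attr(state, id, "bound") / k_inh)
  add_rule(m, rule_first("Cell", rate = cyc_rate, post = function(state, id)
    p_set_attr(state, id, "cycM", p_attr(state, id, "cycM") + 0.01)))
  # a_division sized for the oscillator time step (10 s): terminal speed
  # m*a/gamma ~ 1e-8 m/s moves a child ~r/20 per step, fission in ~40 steps
  add_rule(m, rule_divide("Cell", rate = 1e9, a_division = 3e-8,
    predicate = function(state, id) p_attr(state, id, "cycM") >= 1,
    attrs1 = function(state, id) list(cycM = 0, bound = 0),
    attrs2 = function(state, id)
      list(cycM = 0, bound = 0,
           mating = if (stats::runif(1) < 0.5) "P" else "M")))

  if (k_emit > 0) {
    emit <- function(factor_species, mating_type) {
      rule_first("Cell", rate = k_emit,
        predicate = function(state, id)
          p_attr(state, id, "mating") == mating_type,
        post = function(state, id) {
          r_c <- p_radius(state, id)
          r_f <- 2e-8
          # full-size spawn just outside the emitter: no overlap is created,
          # and a 1/100-size newborn would crash the adaptive time step
          pos <- p_position(state, id) +
            .nf_runif_dir(state$dim) * (r_c + r_f)
          if (.nf_inside_domain(state, pos))
            spawn_particle(state, factor_species, pos, grown = TRUE,
                           check_fit = FALSE)
          invisible(NULL)
        })
    }
    add_rule(m, emit("Pfac", "P"))
    add_rule(m, emit("Mfac", "M"))
    add_rule(m, emit("Sxa2", "M"))
  }
  bind <- function(factor_species, target_mating) {
    rule_bimolecular(factor_species, "Cell", kind = "transform",
      d_star_frac = 0.5, W = 0,
      predicate = function(state, id_f, id_c)
        p_attr(state, id_c, "mating") == target_mating,
      post = function(state, id_f, id_c) {
        p_set_attr(state, id_c, "bound", p_attr(state, id_c, "bound") + 1)
        remove_particles(state, id_f)
      })
  }
  add_rule(m, bind("Pfac", "M"))
  add_rule(m, bind("Mfac", "P"))
  add_rule(m, rule_bimolecular("Sxa2", "Pfac", kind = "transform",
    d_star_frac = 0.5, W = 0,
    post = function(state, id_s, id_p)
      remove_particles(state, c(id_s, id_p))))

  ph <- physics_params(temperature = 310, viscosity = 1e-3,
                       max_timestep = t_step, granularity = 1,
                       domain_lo = rep(0, 2), domain_hi = rep(2e-5, 2),
                       boundary = "absorbing",
                       friction_mode = "semi_implicit")
  st <- new_state(m, ph, seed)
  pts <- .nf_lattice(n_cells, ph$domain_lo + 4e-6, ph$domain_hi - 4e-6, 2)
  ids <- vapply(seq_len(n_cells), function(i)
    spawn_particle(st, "Cell", pts[i, ],
                   attrs = list(mating = if (i %% 2) "P" else "M")),
    integer(1))
  list(state = st, cells = ids)
}

#' Lipid-raft scenario
#'
#' 2D membrane patch with a single static lipid raft covering 25% of the
#' area, whose interior viscosity is 10x the membrane's (so nested proteins
#' diffuse 10x slower). Two protein species start outside the raft: LRP 5/6
#' must cross an entry barrier of W = 12e-21 J to nest into the raft, CK1-g
#' enters freely; both leave without a barrier. The required overlap of the
#' nesting reactions is the full crossing distance (twice the protein
#' radius), so the work against the constant reactive force equals W exactly.
#'
#' @param seed RNG seed.
#' @param n_each number of LRP and of CK1 particles (paper-scale: 200 each).
#' @param W_lrp entry barrier for LRP 5/6 (J).
#' @param box membrane edge length (m).
#' @param r_protein protein radius (m).
#' @return list with the state and the raft id.
#' @export
scenario_raft <- function(seed = 1L, n_each = 200L, W_lrp = 12e-21,
                          box = 1e-6, r_protein = 1e-8) {
  r_raft <- sqrt(0.25 / pi) * box
  m <- new_model(2, contact = TRUE)
  register_species(m, "Raft", radius = r_raft, density = 1000,
                   mobile = FALSE, interior_viscosity = 1e-2)
  register_species(m, "LRP", radius = r_protein, density = 1000)
  register_species(m, "CK1", radius = r_protein, density = 1000)
  ds <- 2 * r_protein
  add_rule(m, rule_bimolecular("LRP", "Raft", kind = "nest", d_star = ds,
                               W = W_lrp))
  add_rule(m, rule_bimolecular("CK1", "Raft", kind = "nest", d_star = ds,
                               W = 0))
  add_rule(m, rule_bimolecular("LRP", "Raft", kind = "unnest", d_star = ds,
                               W = 0))
  add_rule(m, rule_bimolecular("CK1", "Raft", kind = "unnest", d_star = ds,
                               W = 0))
  ph <- physics_params(temperature = 310, viscosity = 1e-3,
                       max_timestep = 5.5e-7, granularity = 1,
                       domain_lo = rep(0, 2), domain_hi = rep(box, 2),
                       friction_mode = "semi_implicit", tol_contain = 1e-9)
  st <- new_state(m, ph, seed)
  raft <- spawn_particle(st, "Raft", rep(box / 2, 2))
  place_outside <- function(sp) {
    repeat {
      pos <- stats::runif(2, r_protein, box - r_protein)
      if (sqrt(sum((pos - box / 2)^2)) > r_raft + 2 * r_protein) break
    }
    spawn_particle(st, sp, pos)
  }
  for (i in seq_len(n_each)) place_outside("LRP")
  for (i in seq_len(n_each)) place_outside("CK1")
  list(state = st, raft = raft)
}

#' In-raft protein counts
#'
#' @param state a raft-scenario state.
#' @return named vector with the number of nested LRP and CK1 particles.
#' @export
raft_counts <- function(state) {
  nested <- state$parent != 0L
  c(LRP = sum(nested & state$species == "LRP"),
    CK1 = sum(nested & state$species == "CK1"))
}
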