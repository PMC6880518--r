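# Independent brute-force collision oracle and small fixture builders.
# The oracle works on dense distance matrices over all particle pairs, with
# none of the grouping/grid machinery of the engine path it checks.

oracle_overlaps <- function(state) {
  n <- state$n
  out <- data.frame(id_a = integer(0), id_b = integer(0), depth = numeric(0),
                    relation = character(0))
  if (n < 2L) return(out)
  pos <- state$pos
  periodic <- state$phys$boundary == "periodic"
  L <- state$phys$domain_hi - state$phys$domain_lo
  acc <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- pos[i, ] - pos[j, ]
      rel <- NULL
      a <- i; b <- j
      if (state$parent[i] == state$parent[j]) {
        rel <- "free_free"
        if (periodic && state$parent[i] == 0L) d <- d - L * round(d / L)
        depth <- state$radius[i] + state$radius[j] - sqrt(sum(d^2))
      } else if (state$parent[i] == state$id[j]) {
        rel <- "inner_shell"
        depth <- sqrt(sum(d^2)) + state$radius[i] - state$radius[j]
      } else if (state$parent[j] == state$id[i]) {
        rel <- "inner_shell"; a <- j; b <- i
        depth <- sqrt(sum(d^2)) + state$radius[j] - state$radius[i]
      }
      if (is.null(rel) || depth <= 0) next
      ida <- state$id[a]; idb <- state$id[b]
      if (rel == "free_free" && ida > idb) { tmp <- ida; ida <- idb; idb <- tmp }
      if (idb %in% state$ignore[[match(ida, state$id)]] ||
          ida %in% state$ignore[[match(idb, state$id)]]) next
      acc[[length(acc) + 1L]] <- data.frame(id_a = ida, id_b = idb,
                                            depth = depth, relation = rel)
    }
  }
  if (!length(acc)) return(out)
  res <- do.call(rbind, acc)
  res[order(res$id_a, res$id_b), , drop = FALSE]
}

expect_overlaps_match_oracle <- function(state, ...) {
  got <- detect_overlaps(state, ...)
  want <- oracle_overlaps(state)
  expect_identical(got$id_a, want$id_a)
  expect_identical(got$id_b, want$id_b)
  expect_equal(got$depth, want$depth, tolerance = 1e-12)
  expect_identical(got$relation, want$relation)
}

# dense-matrix brute force over all n^2 pairs (no grouping, no grid): used for
# the high-volume oracle-equivalence checks; cross-validated against the loop
# oracle above in the collision unit tests
oracle_overlaps_dense <- function(state) {
  n <- state$n
  empty <- data.frame(id_a = integer(0), id_b = integer(0),
                      depth = numeric(0), relation = character(0))
  if (n < 2L) return(empty)
  dd <- 0
  periodic <- state$phys$boundary == "periodic"
  L <- state$phys$domain_hi - state$phys$domain_lo
  top <- state$parent == 0L
  for (k in seq_len(state$dim)) {
    dk <- outer(state$pos[, k], state$pos[, k], "-")
    if (periodic) {
      wrap <- dk - L[k] * round(dk / L[k])
      both_top <- outer(top, top, "&")
      dk[both_top] <- wrap[both_top]
    }
    dd <- dd + dk^2
  }
  dist <- sqrt(dd)
  rsum <- outer(state$radius, state$radius, "+")
  same <- outer(state$parent, state$parent, "==")
  free <- which(upper.tri(dist) & same & (rsum - dist > 0), arr.ind = TRUE)
  child_of <- outer(state$parent, state$id, "==")   # [i, j]: j is i's parent
  shell_depth <- dist + outer(state$radius, rep(0, n), "+") -
    outer(rep(0, n), state$radius, "+")
  shell <- which(child_of & shell_depth > 0, arr.ind = TRUE)
  rows <- list()
  if (nrow(free)) {
    i <- free[, 1]; j <- free[, 2]
    ida <- pmin(state$id[i], state$id[j])
    idb <- pmax(state$id[i], state$id[j])
    rows$free <- data.frame(id_a = ida, id_b = idb,
                            depth = rsum[free] - dist[free],
                            relation = "free_free")
  }
  if (nrow(shell))
    rows$shell <- data.frame(id_a = state$id[shell[, 1]],
                             id_b = state$id[shell[, 2]],
                             depth = shell_depth[shell],
                             relation = "inner_shell")
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  drop <- vapply(seq_len(nrow(res)), function(k) {
    res$id_b[k] %in% state$ignore[[match(res$id_a[k], state$id)]] ||
      res$id_a[k] %in% state$ignore[[match(res$id_b[k], state$id)]]
  }, logical(1))
  res <- res[!drop, , drop = FALSE]
  res <- res[order(res$id_a, res$id_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# a random configuration with a few containers holding contents, the rest
# free spheres; sizes chosen so nesting is geometrically consistent
random_config <- function(seed, n_total, box = 2e-5) {
  set.seed(seed)
  m <- new_model(3)
  register_species(m, "Big", radius = 2e-6)
  register_species(m, "Small", radius = 5e-7)
  ph <- physics_params(domain_lo = rep(0, 3), domain_hi = rep(box, 3))
  st <- new_state(m, ph, seed)
  n_big <- min(3L, n_total %/% 4L)
  bigs <- integer(n_big)
  for (k in seq_len(n_big))
    bigs[k] <- spawn_particle(st, "Big", runif(3, 2e-6, box - 2e-6))
  for (k in seq_len(n_total - n_big)) {
    if (n_big && runif(1) < 0.3) {
      host <- sample(bigs, 1L)
      pos <- p_position(st, host) + nestforce:::.nf_runif_ball(3) * 1.4e-6
      spawn_particle(st, "Small", pos, parent = host)
    } else {
      spawn_particle(st, "Small", runif(3, 5e-7, box - 5e-7))
    }
  }
  st
}

# a state where neither the thermal-speed floor nor the stability guard can
# bind, so the bare adaptive time-step formula is observable
formula_state <- function(v = 1e-2, r = 1e-7, g = 10) {
  m <- new_model(3)
  register_species(m, "H", radius = r, density = 1e6)   # heavy
  ph <- physics_params(temperature = 0, viscosity = 1e-6, granularity = g,
                       max_timestep = 1, domain_lo = rep(0, 3),
                       domain_hi = rep(1e-3, 3))
  st <- new_state(m, ph, 1)
  spawn_particle(st, "H", rep(5e-4, 3), velocity = c(v, 0, 0))
  st
}

# minimal one-species world for unit tests
tiny_state <- function(seed = 1L, dim = 3L, temperature = 310,
                       boundary = "reflective", contact = TRUE, ...) {
  m <- new_model(dim, contact = contact)
  register_species(m, "A", radius = 1e-6, density = 1000)
  ph <- physics_params(temperature = temperature,
                       domain_lo = rep(0, dim), domain_hi = rep(1e-4, dim),
                       boundary = boundary, ...)
  new_state(m, ph, seed)
}
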