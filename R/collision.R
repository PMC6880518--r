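#' Overlap depth between two particles
#'
#' Classifies and measures a geometric overlap. Siblings in the containment
#' forest overlap as free spheres, `d = r_a + r_b - |x_a - x_b|`; a particle
#' against its own container's shell overlaps from inside,
#' `d = (|x_a - x_b| + r_a) - r_b` (the protrusion beyond the shell). Pairs
#' that are neither siblings nor parent-child are never in contact (the shell
#' mediates all cross-compartment interaction) and raise a classification
#' error. `crossing_shell` (a nesting/unnesting in progress) uses the same
#' formula family evaluated against the shell being crossed.
#'
#' @param state an `nf_state`.
#' @param id_a,id_b particle ids; for `inner_shell`, `id_b` is the shell.
#' @param relation optional override: `"free_free"`, `"inner_shell"` or
#'   `"crossing_shell"`; by default classified from the parent links.
#' @return list with `depth` (m; 0 when disjoint), `relation`, `distance`.
#' @export
overlap_depth <- function(state, id_a, id_b, relation = NULL) {
  ra <- .nf_row(state, id_a)
  rb <- .nf_row(state, id_b)
  if (is.null(relation)) {
    if (state$parent[ra] == state$parent[rb]) relation <- "free_free"
    else if (state$parent[ra] == id_b) relation <- "inner_shell"
    else if (state$parent[rb] == id_a) { # swap so a is the inner particle
      tmp <- ra; ra <- rb; rb <- tmp
      relation <- "inner_shell"
    } else stop("particles ", id_a, " and ", id_b, " are neither siblings ",
                "nor parent and child: no contact relation", call. = FALSE)
  }
  dvec <- .nf_pair_diff(state, state$pos[ra, , drop = FALSE],
                        state$pos[rb, , drop = FALSE],
                        top = state$parent[ra] == 0L && state$parent[rb] == 0L)
  dist <- sqrt(sum(dvec^2))
  depth <- if (relation == "free_free")
    state$radius[ra] + state$radius[rb] - dist
  else dist + state$radius[ra] - state$radius[rb]
  list(depth = max(depth, 0), relation = relation, distance = dist)
}

# pairwise difference x_a - x_b with minimum image when both particles are
# top-level in a periodic domain
.nf_pair_diff <- function(state, xa, xb, top = TRUE) {
  d <- xa - xb
  if (top && state$phys$boundary == "periodic") {
    L <- state$phys$domain_hi - state$phys$domain_lo
    d <- d - rep(L, each = nrow(d)) * round(d / rep(L, each = nrow(d)))
  }
  d
}

# all unordered pairs of 1..k as a 2-column matrix
.nf_all_pairs <- function(k) {
  if (k < 2L) return(matrix(integer(0), 0L, 2L))
  ia <- rep.int(seq_len(k - 1L), (k - 1L):1L)
  ib <- sequence((k - 1L):1L) + ia
  cbind(ia, ib)
}

#' Uniform-grid broad phase
#'
#' Bins particle centres into a uniform cell grid with edge length at least
#' twice the largest radius of the group, and returns every pair sharing a
#' cell or sitting in adjacent cells: a superset of all truly overlapping
#' pairs. Used for large sibling groups; small groups go through the exact
#' all-pairs narrow phase directly.
#'
#' @param pos `k x dim` position matrix of one sibling group.
#' @param radius radii of the group.
#' @return 2-column integer matrix of candidate index pairs (into the group).
#' @export
build_broadphase <- function(pos, radius) {
  k <- nrow(pos)
  if (k < 2L) return(matrix(integer(0), 0L, 2L))
  cell <- max(2 * max(radius), 1e-300)
  # pad the index range by one ghost cell per side so that linear-index
  # neighbour arithmetic never aliases across axis boundaries
  ci <- floor(sweep(pos, 2, apply(pos, 2, min)) / cell) + 1L
  dims <- apply(ci, 2, max) + 2L
  mult <- cumprod(c(1, dims[-length(dims)]))
  lin <- as.integer(ci %*% mult)
  byc <- split(seq_len(k), lin)
  # forward neighbour offsets (half space) to emit each cell pair once
  dim <- ncol(pos)
  offs <- as.matrix(expand.grid(rep(list(-1:1), dim)))
  offs <- offs[apply(offs, 1, function(o) {
    nz <- which(o != 0)
    length(nz) > 0 && o[nz[length(nz)]] > 0
  }), , drop = FALSE]
  off_lin <- as.integer(offs %*% mult)
  keys <- as.integer(names(byc))
  keyset <- new.env(parent = emptyenv())
  for (i in seq_along(keys)) assign(as.character(keys[i]), i, envir = keyset)
  out <- vector("list", length(keys) * 2L)
  nout <- 0L
  for (i in seq_along(keys)) {
    members <- byc[[i]]
    if (length(members) > 1L) {
      nout <- nout + 1L
      pr <- .nf_all_pairs(length(members))
      out[[nout]] <- cbind(members[pr[, 1]], members[pr[, 2]])
    }
    for (ol in off_lin) {
      j <- get0(as.character(keys[i] + ol), envir = keyset)
      if (is.null(j)) next
      other <- byc[[j]]
      nout <- nout + 1L
      out[[nout]] <- cbind(rep(members, each = length(other)),
                           rep(other, length(members)))
    }
  }
  if (nout == 0L) return(matrix(integer(0), 0L, 2L))
  do.call(rbind, out[seq_len(nout)])
}

#' Detect all geometric overlaps
#'
#' Produces exactly the set of positive-depth overlap pairs among (i) siblings
#' of the containment forest and (ii) each contained particle against its own
#' parent's shell, minus pairs suppressed by an ignore relation (installed
#' temporarily during compartment division). Pairs are returned in a
#' deterministic order, sorted by id pair with `id_a < id_b` for free pairs
#' and (inner, shell) orientation for shell pairs.
#'
#' The contact normal is reported on particle `a`: for free pairs it points
#' from `b` toward `a` (the push-apart direction); for inner-shell pairs it
#' points from the inner particle toward the container centre (the inward
#' push).
#'
#' @param state an `nf_state`.
#' @param grid_threshold group size above which the uniform-grid broad phase
#'   is used instead of exact all-pairs (never for periodic domains, which use
#'   minimum-image all-pairs).
#' @return an `nf_overlaps` list of parallel vectors: `row_a`, `row_b`,
#'   `id_a`, `id_b`, `depth`, `distance`, `relation`, and `normal`
#'   (`npairs x dim` matrix).
#' @export
detect_overlaps <- function(state, grid_threshold = 150L) {
  n <- state$n
  dim <- state$dim
  acc_a <- integer(0); acc_b <- integer(0)
  acc_d <- numeric(0); acc_dist <- numeric(0)
  acc_rel <- character(0)
  acc_nrm <- matrix(numeric(0), 0L, dim)
  periodic <- state$phys$boundary == "periodic"

  groups <- split(seq_len(n), state$parent)
  for (gname in names(groups)) {
    g <- groups[[gname]]
    k <- length(g)
    if (k >= 2L) {
      top <- gname == "0"
      use_grid <- k > grid_threshold && !(top && periodic)
      pr <- if (use_grid)
        build_broadphase(state$pos[g, , drop = FALSE], state$radius[g])
      else .nf_all_pairs(k)
      if (nrow(pr)) {
        ga <- g[pr[, 1]]; gb <- g[pr[, 2]]
        dvec <- .nf_pair_diff(state, state$pos[ga, , drop = FALSE],
                              state$pos[gb, , drop = FALSE], top = top)
        dist <- sqrt(rowSums(dvec^2))
        depth <- state$radius[ga] + state$radius[gb] - dist
        hit <- which(depth > 0)
        if (length(hit)) {
          acc_a <- c(acc_a, ga[hit]); acc_b <- c(acc_b, gb[hit])
          acc_d <- c(acc_d, depth[hit]); acc_dist <- c(acc_dist, dist[hit])
          acc_rel <- c(acc_rel, rep("free_free", length(hit)))
          nrm <- dvec[hit, , drop = FALSE] / ifelse(dist[hit] > 0, dist[hit], 1)
          acc_nrm <- rbind(acc_nrm, nrm)
        }
      }
    }
    # contained particles against this group's shell (gname = parent id)
    if (gname != "0") {
      prow <- match(as.integer(gname), state$id)
      dvec <- .nf_pair_diff(state, state$pos[g, , drop = FALSE],
                            state$pos[rep(prow, k), , drop = FALSE],
                            top = FALSE)
      dist <- sqrt(rowSums(dvec^2))
      depth <- dist + state$radius[g] - state$radius[prow]
      hit <- which(depth > 0)
      if (length(hit)) {
        acc_a <- c(acc_a, g[hit]); acc_b <- c(acc_b, rep(prow, length(hit)))
        acc_d <- c(acc_d, depth[hit]); acc_dist <- c(acc_dist, dist[hit])
        acc_rel <- c(acc_rel, rep("inner_shell", length(hit)))
        # inward: from the inner particle toward the container centre
        nrm <- -dvec[hit, , drop = FALSE] / ifelse(dist[hit] > 0, dist[hit], 1)
        acc_nrm <- rbind(acc_nrm, nrm)
      }
    }
  }

  if (length(acc_a)) {
    # canonical orientation for free pairs: id_a < id_b
    swap <- acc_rel == "free_free" & state$id[acc_a] > state$id[acc_b]
    if (any(swap)) {
      tmp <- acc_a[swap]; acc_a[swap] <- acc_b[swap]; acc_b[swap] <- tmp
      acc_nrm[swap, ] <- -acc_nrm[swap, , drop = FALSE]
    }
    # ignore relations (only pairs touching a particle with a non-empty set)
    drop <- logical(length(acc_a))
    has_ign <- lengths(state$ignore) > 0L
    for (k in which(has_ign[acc_a] | has_ign[acc_b]))
      drop[k] <- state$id[acc_b[k]] %in% state$ignore[[acc_a[k]]] ||
        state$id[acc_a[k]] %in% state$ignore[[acc_b[k]]]
    keep <- which(!drop)
    ord <- keep[order(state$id[acc_a[keep]], state$id[acc_b[keep]])]
    acc_a <- acc_a[ord]; acc_b <- acc_b[ord]
    acc_d <- acc_d[ord]; acc_dist <- acc_dist[ord]
    acc_rel <- acc_rel[ord]
    acc_nrm <- acc_nrm[ord, , drop = FALSE]
  }
  structure(list(row_a = acc_a, row_b = acc_b,
                 id_a = state$id[acc_a], id_b = state$id[acc_b],
                 depth = acc_d, distance = acc_dist, relation = acc_rel,
                 normal = acc_nrm, n = length(acc_a)),
            class = "nf_overlaps")
}
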