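#' Estimate a rate constant from a count time series
#'
#' Order 1: log-linear regression of `log(count)` on time; the decay rate is
#' minus the slope. Order 2 (equal reactant counts, A + B -> C with
#' N_A = N_B = N): regression of `1/N` on time; for mass-action kinetics
#' `d(1/N)/dt = k / V`, so the returned rate is the slope and the caller
#' scales by the reaction volume to obtain the macroscopic rate constant.
#'
#' @param times sampling times (s).
#' @param counts particle counts at those times.
#' @param order reaction order, 1 or 2.
#' @return list with `rate`, its standard error `se`, and the 95% confidence
#'   interval `ci`.
#' @export
estimate_rate <- function(times, counts, order = 1) {
  stopifnot(length(times) == length(counts), order %in% c(1, 2))
  keep <- counts > 0
  if (sum(keep) < 3)
    stop("insufficient data to estimate a rate: need >= 3 positive counts ",
         "(have ", sum(keep), ")", call. = FALSE)
  y <- if (order == 1) log(counts[keep]) else 1 / counts[keep]
  fit <- stats::lm(y ~ times[keep])
  slope <- unname(stats::coef(fit)[2])
  se <- unname(sqrt(diag(stats::vcov(fit)))[2])
  rate <- if (order == 1) -slope else slope
  list(rate = rate, se = se, ci = rate + c(-1, 1) * 1.96 * se)
}

#' Ensemble mean squared displacement
#'
#' Averages squared displacements over all particles and over all time
#' origins of a trajectory recorded at a fixed frame spacing. The long-time
#' slope of the returned curve is `2 d D` for free diffusion in `d`
#' dimensions.
#'
#' @param frames trajectory frames (a trajectory observer's `$data()`); all
#'   frames must contain the same particles in the same order.
#' @param lags lag times, in frames (integers >= 1).
#' @return data.frame with columns `lag` (frames), `dt` (s) and `msd` (m^2).
#' @export
msd <- function(frames, lags) {
  nT <- length(frames)
  stopifnot(nT >= 2, all(lags >= 1), all(lags < nT))
  n <- frames[[1]]$n
  for (fr in frames) if (fr$n != n || !identical(fr$id, frames[[1]]$id))
    stop("msd() needs a constant particle set across frames", call. = FALSE)
  out <- vapply(lags, function(L) {
    tot <- 0; cnt <- 0L
    for (t0 in seq_len(nT - L)) {
      d <- frames[[t0 + L]]$pos - frames[[t0]]$pos
      tot <- tot + sum(d * d)
      cnt <- cnt + n
    }
    tot / cnt
  }, numeric(1))
  tgrid <- vapply(frames, function(fr) fr$time, numeric(1))
  data.frame(lag = lags, dt = lags * diff(tgrid)[1], msd = out)
}

#' Occupancy of a container
#'
#' Fraction of the particles of a species that are contained (directly) in a
#' particle of the container species, per frame.
#'
#' @param frames trajectory frames (see [msd()]), or a single `nf_state`.
#' @param species species of interest.
#' @param container_species container species name.
#' @return data.frame with columns `time` and `occupancy` (or a single number
#'   for a state).
#' @export
occupancy <- function(frames, species, container_species) {
  one <- function(sp, parent, id, time) {
    sel <- sp == species
    if (!any(sel)) return(NA_real_)
    inside <- parent[sel] != 0L &
      sp[match(parent[sel], id)] == container_species
    mean(inside, na.rm = TRUE)
  }
  if (inherits(frames, "nf_state"))
    return(one(frames$species, frames$parent, frames$id, frames$time))
  data.frame(
    time = vapply(frames, function(fr) fr$time, numeric(1)),
    occupancy = vapply(frames, function(fr)
      one(fr$species, fr$parent, fr$id, fr$time), numeric(1)))
}
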