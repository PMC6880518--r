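#' Physical constants and unit helpers
#'
#' The simulator works in strict SI units internally (m, s, kg, K, J, Pa.s).
#' Model code is expected to express quantities through these helpers rather
#' than raw magic numbers, which keeps mixed micrometre/minute parameter sets
#' honest.
#'
#' @format `nf_units` is a named list of multiplicative conversion factors to
#'   SI plus the Boltzmann constant `kB` (J/K, CODATA 2018 exact value).
#' @examples
#' 2.5 * nf_units$um     # 2.5 micrometres in metres
#' 120 * nf_units$minute # 120 minutes in seconds
#' @export
nf_units <- list(
  # lengths
  m = 1, um = 1e-6, nm = 1e-9,
  # times
  s = 1, ms = 1e-3, us = 1e-6, ns = 1e-9, minute = 60, hour = 3600,
  # masses / densities
  kg = 1, g_per_cm3 = 1000,
  # energy, force, pressure, viscosity
  J = 1, pN = 1e-12, Pa = 1, mPa_s = 1e-3,
  # Boltzmann constant (J/K)
  kB = 1.380649e-23
)

#' @rdname nf_units
#' @export
nf_kB <- nf_units$kB
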