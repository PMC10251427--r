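# Unit conversion factors used throughout.  Internally all pressures are kept
# in mmHg, all flows in m^3/s and all hydraulic conductances in
# m^3 s^-1 mmHg^-1 (the units of the printed calibration constants);
# microlitres per minute appear only at I/O boundaries.
.MMHG_PA <- 133.322        # Pa per mmHg
.ULMIN_M3S <- 1e-9 / 60    # m^3/s per uL/min

.PRESSURE_UNITS <- c("mmHg", "Pa")
.FLOW_UNITS <- c("uL/min", "m3/s")

#' Convert a hydraulic pressure between mmHg and Pa
#'
#' Exact linear conversion with 1 mmHg = 133.322 Pa.
#'
#' @param value numeric vector of pressures.
#' @param from,to unit names, one of `"mmHg"` or `"Pa"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_pressure(1950, "Pa", "mmHg")  # ~14.63 mmHg
#' @export
convert_pressure <- function(value, from, to) {
  from <- match.arg(from, .PRESSURE_UNITS)
  to <- match.arg(to, .PRESSURE_UNITS)
  stopifnot(is.numeric(value))
  pa <- if (from == "Pa") value else value * .MMHG_PA
  if (to == "Pa") pa else pa / .MMHG_PA
}

#' Convert a volumetric flow rate between uL/min and m^3/s
#'
#' Exact linear conversion with 1 uL/min = 1e-9/60 m^3/s.
#'
#' @param value numeric vector of flow rates.
#' @param from,to unit names, one of `"uL/min"` or `"m3/s"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_flow(2.75, "uL/min", "m3/s")  # 4.583e-11 m^3/s
#' @export
convert_flow <- function(value, from, to) {
  from <- match.arg(from, .FLOW_UNITS)
  to <- match.arg(to, .FLOW_UNITS)
  stopifnot(is.numeric(value))
  si <- if (from == "m3/s") value else value * .ULMIN_M3S
  if (to == "m3/s") si else si / .ULMIN_M3S
}

#' Specific hydraulic conductance of a plane Poiseuille channel
#'
#' For fully developed laminar flow between parallel walls a distance `2a`
#' apart over a length `b`, the mean axial velocity is proportional to the
#' pressure drop: `V = K * dp` with `K = 2 a^2 / (3 mu b)`.  This is the
#' discrete Darcy/Poiseuille law underlying the compartment conductances of
#' the posterior and anterior chambers (which themselves are obtained by
#' calibration, not from geometry, because the effective cross-sections are
#' not measurable).
#'
#' @param a channel half-height (m).
#' @param b channel length (m).
#' @param mu dynamic viscosity (Pa s).
#' @return specific hydraulic conductance (m s^-1 Pa^-1).
#' @export
poiseuille_specific_conductance <- function(a, b, mu) {
  if (any(!is.finite(a)) || any(a <= 0)) stop("`a` must be positive and finite")
  if (any(!is.finite(b)) || any(b <= 0)) stop("`b` must be positive and finite")
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("`mu` must be positive and finite")
  2 * a^2 / (3 * mu * b)
}
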