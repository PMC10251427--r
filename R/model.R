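#' Hill saturation function
#'
#' `f(xi) = beta * xi^p / (xi^p + k_act^p)`: sigmoidal, monotone
#' nondecreasing, `f(0) = 0`, `f(k_act) = beta/2`, bounded above by `beta`.
#' Both unconventional-route nonlinearities (pressure-activated conductance
#' gain and drug-activated flow source) are Hill laws with exponent 4.
#'
#' @param xi non-negative numeric vector (activation variable).
#' @param params list with fields `beta`, `k_act` (> 0) and `p` (>= 1), e.g.
#'   `model$hill_hyd` or `model$hill_drug`.
#' @return numeric vector, same length as `xi`.
#' @export
hill <- function(xi, params) {
  if (any(!is.finite(xi)) || any(xi < 0))
    stop("`xi` must be finite and non-negative")
  beta <- params$beta; k <- params$k_act; p <- params$p
  if (beta == 0) return(rep(0, length(xi)))
  if (!is.finite(k) || k <= 0) stop("Hill `k_act` must be a positive number")
  # evaluate on the ratio scale so large xi cannot overflow xi^p
  r <- (xi / k)^p
  ifelse(is.infinite(r), beta, beta * r / (r + 1))
}

#' Pressure-deviation variable Z(x)
#'
#' `Z(x) = max((x - x_b) / (x_b - P_b), 0)`: the relative elevation of IOP
#' above baseline, normalised by `x_b - P_b` (with `P_b = p_s + R_ac_b * Q_b`
#' and the secreted flow, suprachoroidal pressure and anterior chamber
#' resistance frozen at baseline).  The clamp at zero is a hard kink by
#' design: no hydraulic adaptation is recruited below baseline IOP.
#'
#' @param x IOP (mmHg), vectorised.
#' @param model an [calibrate()]d model.
#' @return dimensionless numeric vector.
#' @export
z_of_x <- function(x, model) {
  pmax((x - model$baseline$x_b) / model$denom_Z, 0)
}

#' Pressure-dependent unconventional (uveoscleral) conductance
#'
#' `L_unc(Z) = L_unc_b * (1 + f_H(Z; kappa_hyd * beta_max_hyd, k_act_hyd, p))`.
#' Equals `L_unc_b` when `Z = 0` or `kappa_hyd = 0` (linear resistor model);
#' saturates at `L_unc_b * (1 + beta)`.
#'
#' @param Z non-negative pressure-deviation value(s), see [z_of_x()].
#' @param model an [calibrate()]d model.
#' @return conductance (m^3 s^-1 mmHg^-1), vectorised over `Z`.
#' @export
l_unc_hyd <- function(Z, model) {
  model$L_unc_b * (1 + hill(Z, model$hill_hyd))
}

#' Drug-dependent unconventional flow source
#'
#' `Q_unc_drug(m) = f_H(m; kappa_drug * beta_max_drug, k_act_drug, p)`:
#' a flow source controlled solely by the cumulative absorbed drug mass,
#' independent of IOP, saturating at `kappa_drug * beta_max_drug`.
#'
#' @param m_abs cumulative absorbed drug mass (ug), vectorised.
#' @param model an [calibrate()]d model.
#' @return flow (m^3/s).
#' @export
q_unc_drug <- function(m_abs, model) {
  if (model$hill_drug$beta == 0) return(rep(0, length(m_abs)))
  hill(m_abs, model$hill_drug)
}

#' Cumulative absorbed drug mass after a number of daily drops
#'
#' `m(day) = f_bio * m_onedrop * day`.  Time enters the model only through
#' this parametric mass; day `n_days` gives the regimen total `m_tot_abs`.
#'
#' @param day integer day count (0 = no drug), vectorised.
#' @param regimen a [drug_regimen()].
#' @return absorbed mass (ug).
#' @export
absorbed_mass <- function(day, regimen) {
  if (any(!is.finite(day)) || any(day < 0) || any(day != round(day)))
    stop("`day` must be a non-negative integer")
  regimen$f_bio * regimen$m_onedrop * day
}

#' Define a steady-state scenario
#'
#' A scenario is one steady-state problem instance: a calibrated model, a
#' trabecular resistance multiplier `eta = R_conv / R_conv_b` (1 = healthy,
#' 3 = reference pathological value) and a cumulative absorbed drug mass.
#'
#' @param model an [calibrate()]d model.
#' @param eta trabecular resistance multiplier (> 0).
#' @param m_abs absorbed drug mass (ug, >= 0).
#' @return an object of class `aq_scenario`.
#' @export
scenario <- function(model, eta = 1, m_abs = 0) {
  stopifnot(inherits(model, "aq_model"))
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta <= 0)
    stop("`eta` must be a single positive number")
  if (!is.numeric(m_abs) || length(m_abs) != 1L || !is.finite(m_abs) || m_abs < 0)
    stop("`m_abs` must be a single non-negative number")
  structure(list(model = model, eta = as.numeric(eta), m_abs = as.numeric(m_abs)),
            class = "aq_scenario")
}

#' Constants of the iteration map for a scenario
#'
#' Precomputes the scenario-level constants of the fixed-point map:
#' `R_conv = eta / L_conv_b`, `R_tot = R_conv + R_ac_b`,
#' `P_tilde = p_ev + R_tot * Q_b` (the IOP the circuit would attain with the
#' unconventional route removed) and the drug offset
#' `phi_tilde = R_conv * Q_unc_drug(m)`.
#'
#' @param scen an [scenario()].
#' @return list with `R_conv`, `R_tot`, `P_tilde`, `phi_tilde` (pressures in
#'   mmHg, resistances in mmHg s m^-3).
#' @export
map_constants <- function(scen) {
  m <- scen$model
  R_conv <- scen$eta * m$R_conv_b
  R_tot <- R_conv + m$R_ac_b
  list(
    R_conv = R_conv,
    R_tot = R_tot,
    P_tilde = m$baseline$p_ev + R_tot * m$baseline$q_total,
    phi_tilde = R_conv * q_unc_drug(scen$m_abs, m)
  )
}

#' Fixed-point iteration map T_m(x)
#'
#' One application of the steady-state map whose fixed point is the IOP:
#' `T_m(x) = (P_tilde - phi_tilde + P_b * phi(x)) / (1 + phi(x))` with
#' `phi(x) = R_conv * L_unc(Z(x))`.  With `kappa_hyd = 0` the map is constant
#' in `x` and the fixed point has the closed form `T_m(anything)`.
#'
#' @param x IOP (mmHg), vectorised.
#' @param scen an [scenario()].
#' @param consts optional precomputed [map_constants()] (for tight loops).
#' @return mapped IOP (mmHg).
#' @export
iteration_map <- function(x, scen, consts = map_constants(scen)) {
  phi <- consts$R_conv * l_unc_hyd(z_of_x(x, scen$model), scen$model)
  (consts$P_tilde - consts$phi_tilde + scen$model$P_b * phi) / (1 + phi)
}

#' Recover the full circuit state from a solved IOP
#'
#' Back-substitutes a solved IOP `x` through the Kirchhoff/Ohm relations:
#' posterior chamber pressure `z = x + Q_b / L_pc`, anterior chamber pressure
#' `y = x - Q_b / L_ac`, unconventional driving pressure `w = y - p_s`, the
#' branch flows, and the residual `x - T_m(x)`.
#'
#' @param x solved IOP (mmHg).
#' @param scen the [scenario()] that was solved.
#' @param iterations iteration count reported by the solver.
#' @param method one of `"fixed_point"`, `"closed_form_linear"`,
#'   `"bracketed_root"`.
#' @return an object of class `aq_state`: pressures in mmHg, flows in m^3/s.
#' @export
recover_state <- function(x, scen, iterations = NA_integer_,
                          method = c("fixed_point", "closed_form_linear",
                                     "bracketed_root")) {
  method <- match.arg(method)
  m <- scen$model
  b <- m$baseline
  consts <- map_constants(scen)
  z <- x + b$q_total / m$L_pc
  y <- x - b$q_total / m$L_ac
  w <- y - b$p_s
  q_unc_hyd <- l_unc_hyd(z_of_x(x, m), m) * w
  q_unc_drug_v <- q_unc_drug(scen$m_abs, m)
  structure(
    list(
      x = x, z = z, y = y, w = w,
      Z_val = z_of_x(x, m),
      Q12 = m$L_pc * (z - x),
      Q23 = m$L_ac * (x - y),
      Q_conv = (m$L_conv_b / scen$eta) * (y - b$p_ev),
      Q_unc_hyd = q_unc_hyd,
      Q_unc_drug = q_unc_drug_v,
      Q_unc = q_unc_hyd + q_unc_drug_v,
      residual = x - iteration_map(x, scen, consts),
      iterations = as.integer(iterations),
      method = method,
      scenario = scen
    ),
    class = "aq_state"
  )
}

#' @export
print.aq_state <- function(x, ...) {
  f <- function(q) convert_flow(q, "m3/s", "uL/min")
  cat(sprintf("Steady state (eta = %g, m_abs = %g ug, method = %s, k = %s)\n",
              x$scenario$eta, x$scenario$m_abs, x$method,
              ifelse(is.na(x$iterations), "?", x$iterations)))
  cat(sprintf("  IOP = %.4f mmHg  (p_pc = %.4f, p_ac = %.4f mmHg)\n",
              x$x, x$z, x$y))
  cat(sprintf("  Q_conv = %.4f, Q_unc = %.4f (hyd %.4f + drug %.4f) uL/min\n",
              f(x$Q_conv), f(x$Q_unc), f(x$Q_unc_hyd), f(x$Q_unc_drug)))
  cat(sprintf("  residual x - T(x) = %.3g mmHg\n", x$residual))
  invisible(x)
}
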