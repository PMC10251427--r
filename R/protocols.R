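# Turn a list of solved states into one tidy sweep row (reporting units:
# mmHg and uL/min).
.state_row <- function(st) {
  f <- function(q) convert_flow(q, "m3/s", "uL/min")
  data.frame(
    iop_mmHg = st$x, p_pc_mmHg = st$z, p_ac_mmHg = st$y,
    q_conv_ul_min = f(st$Q_conv), q_unc_ul_min = f(st$Q_unc),
    q_unc_hyd_ul_min = f(st$Q_unc_hyd), q_unc_drug_ul_min = f(st$Q_unc_drug),
    residual_mmHg = st$residual, iterations = st$iterations,
    method = st$method, stringsAsFactors = FALSE
  )
}

.as_sweep <- function(rows, axis, model, config) {
  structure(rows, class = c("aq_sweep", "data.frame"),
            axis = axis, model = model, config = config)
}

#' Phase 1: progressive elevation of trabecular resistance (no drug)
#'
#' Sweeps the trabecular resistance multiplier `eta` over a uniform grid on
#' `[1, eta_max]` with the drug source off, solving each steady state.  This
#' is the glaucomatous-onset experiment: it quantifies how much of the IOP
#' rise the pressure-dependent unconventional route relieves.
#'
#' @param model an [calibrate()]d model.
#' @param eta_max upper end of the resistance multiplier grid (default 3, the
#'   reference pathological value).
#' @param n_steps number of grid points (default 201).
#' @param kappa_hyd optional override of the model's pressure-route gain
#'   (model is recalibrated with the new gain).
#' @param config optional [solver_config()].
#' @return an `aq_sweep` data frame, one row per `eta`, with the solved IOP,
#'   pressures and flow decomposition in reporting units (mmHg, uL/min).
#' @export
run_phase1 <- function(model, eta_max = 3, n_steps = 201L, kappa_hyd = NULL,
                       config = NULL) {
  stopifnot(inherits(model, "aq_model"))
  if (eta_max < 1) stop("`eta_max` must be >= 1")
  if (n_steps < 2) stop("`n_steps` must be >= 2")
  if (!is.null(kappa_hyd)) model <- .with_kappa(model, kappa_hyd = kappa_hyd)
  if (is.null(config)) config <- solver_config(model)
  etas <- seq(1, eta_max, length.out = n_steps)
  rows <- lapply(etas, function(eta) {
    st <- tryCatch(solve_fixed_point(scenario(model, eta = eta, m_abs = 0), config,
                                     on_failure = "bracket"),
                   error = function(e) stop(sprintf("phase 1 solve failed at eta = %g: %s",
                                                    eta, conditionMessage(e)), call. = FALSE))
    cbind(data.frame(eta = eta), .state_row(st))
  })
  .as_sweep(do.call(rbind, rows), axis = "eta", model = model, config = config)
}

#' Phase 2: daily drug therapy at fixed pathological resistance
#'
#' Keeps the trabecular resistance at `eta_path` times baseline and increases
#' the cumulative absorbed drug mass day by day (`m(day) = f_bio * m_onedrop
#' * day`), solving each steady state.  Day 0 reproduces the Phase-1 endpoint.
#'
#' @param model an [calibrate()]d model.
#' @param regimen a [drug_regimen()]; defaults to the model's.
#' @param eta_path fixed resistance multiplier (default 3).
#' @param kappa_hyd optional override of the pressure-route gain.
#' @param config optional [solver_config()].
#' @return an `aq_sweep` data frame, one row per day, including the percent
#'   IOP reduction relative to the day-0 (pathological) value
#'   (`iop_reduction_pct`).
#' @export
run_phase2 <- function(model, regimen = model$regimen, eta_path = 3,
                       kappa_hyd = NULL, config = NULL) {
  stopifnot(inherits(model, "aq_model"), inherits(regimen, "aq_regimen"))
  if (eta_path <= 0) stop("`eta_path` must be positive")
  if (!is.null(kappa_hyd)) model <- .with_kappa(model, kappa_hyd = kappa_hyd)
  if (is.null(config)) config <- solver_config(model)
  days <- 0:regimen$n_days
  rows <- lapply(days, function(d) {
    m_abs <- absorbed_mass(d, regimen)
    st <- tryCatch(solve_fixed_point(scenario(model, eta = eta_path, m_abs = m_abs), config,
                                     on_failure = "bracket"),
                   error = function(e) stop(sprintf("phase 2 solve failed at day %d: %s",
                                                    d, conditionMessage(e)), call. = FALSE))
    cbind(data.frame(day = d, m_abs_ug = m_abs), .state_row(st))
  })
  out <- do.call(rbind, rows)
  out$iop_reduction_pct <- 100 * (out$iop_mmHg[1] - out$iop_mmHg) / out$iop_mmHg[1]
  .as_sweep(out, axis = "day", model = model, config = config)
}

#' Sensitivity of IOP to the trabecular resistance multiplier (linear regime)
#'
#' Closed-form derivative `S_x(eta) = dx/deta` of the linear-model
#' (`kappa_hyd = 0`) steady state:
#' `S_x = R_conv_b * (Q_b / (1 + phi) + L_unc_b * (P_b - P_tilde) / (1 + phi)^2)`
#' with `phi = eta * R_conv_b * L_unc_b` and
#' `P_tilde = p_ev + (eta * R_conv_b + R_ac_b) * Q_b` evaluated at the current
#' `eta`, which makes the expression the exact derivative of the closed-form
#' linear solution.  It is positive (IOP keeps rising with resistance) and
#' monotonically decreasing (the rise flattens), with saturation only at
#' unphysiologically large resistance.
#'
#' @param model an [calibrate()]d model (only baseline conductances enter;
#'   the formula describes the `kappa_hyd = 0` regime).
#' @param eta resistance multiplier(s), vectorised.
#' @return sensitivity in mmHg per unit `eta`.
#' @export
sensitivity_eta <- function(model, eta) {
  stopifnot(inherits(model, "aq_model"))
  if (any(eta <= 0)) stop("`eta` must be positive")
  b <- model$baseline
  phi <- eta * model$R_conv_b * model$L_unc_b
  P_tilde <- b$p_ev + (eta * model$R_conv_b + model$R_ac_b) * b$q_total
  model$R_conv_b * (b$q_total / (1 + phi) +
                      model$L_unc_b * (model$P_b - P_tilde) / (1 + phi)^2)
}

#' Mass-conservation audit of a sweep
#'
#' In exact arithmetic every converged steady state drains exactly the
#' secreted flow: `Q_conv + Q_unc = Q_b`.  The worst-case deviation over a
#' sweep therefore measures the accuracy of the solve: machine precision for
#' linear (`closed_form_linear`) sweeps, bounded by the iteration tolerance
#' otherwise.
#'
#' @param sweep an `aq_sweep` from [run_phase1()] or [run_phase2()].
#' @return maximum absolute deviation `|Q_conv + Q_unc - Q_b|` (uL/min).
#' @export
mass_audit <- function(sweep) {
  stopifnot(inherits(sweep, "aq_sweep"))
  q_bar <- convert_flow(attr(sweep, "model")$baseline$q_total, "m3/s", "uL/min")
  max(abs(sweep$q_conv_ul_min + sweep$q_unc_ul_min - q_bar))
}

#' @export
print.aq_sweep <- function(x, ...) {
  cat(sprintf("Steady-state sweep over %s (%d rows)\n", attr(x, "axis"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 4), digits = 6)
  if (nrow(x) > 4) cat("  ...\n")
  cat(sprintf("mass audit: max |Q_conv + Q_unc - Q_b| = %.3g uL/min\n",
              mass_audit(x)))
  invisible(x)
}
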