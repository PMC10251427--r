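#' Baseline physiology of the healthy anterior segment
#'
#' Collects the pressures and volumetric flow rates of a healthy eye from
#' which every hydraulic conductance of the circuit is calibrated.  Defaults
#' are the standard healthy-eye values: IOP 15 mmHg, posterior chamber
#' 15.5 mmHg, anterior chamber 1950 Pa (~14.63 mmHg), episcleral vein
#' 8 mmHg, suprachoroidal space 11 mmHg, conventional (trabecular) outflow
#' 2.45 uL/min and hydraulic uveoscleral outflow 0.3 uL/min.
#'
#' The total secreted flow `q_total` defaults to the mass-balanced sum
#' `q_conv + q_unc_hyd` = 2.75 uL/min; an override (e.g. 2.74 uL/min, a value
#' sometimes quoted for the same dataset) is accepted but breaks exact
#' baseline mass balance.
#'
#' @param x_b baseline IOP (mmHg).
#' @param p_pc baseline posterior chamber pressure (mmHg).
#' @param p_ac baseline anterior chamber pressure (mmHg).
#' @param p_ev episcleral vein pressure (mmHg).
#' @param p_s suprachoroidal space pressure (mmHg).
#' @param q_conv baseline conventional-route flow (uL/min).
#' @param q_unc_hyd baseline hydraulic unconventional-route flow (uL/min).
#' @param q_total total secreted flow (uL/min); `NULL` (default) means
#'   `q_conv + q_unc_hyd`.
#' @return an object of class `aq_baseline`: pressures in mmHg, flows stored
#'   in m^3/s (fields `q_conv`, `q_unc_hyd`, `q_total`).
#' @examples
#' b <- baseline_physiology()
#' convert_flow(b$q_total, "m3/s", "uL/min")  # 2.75
#' @export
baseline_physiology <- function(x_b = 15,
                                p_pc = 15.5,
                                p_ac = convert_pressure(1950, "Pa", "mmHg"),
                                p_ev = 8,
                                p_s = 11,
                                q_conv = 2.45,
                                q_unc_hyd = 0.3,
                                q_total = NULL) {
  num1 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("baseline field `%s` must be a single finite number", nm))
    as.numeric(v)
  }
  x_b <- num1(x_b, "x_b"); p_pc <- num1(p_pc, "p_pc"); p_ac <- num1(p_ac, "p_ac")
  p_ev <- num1(p_ev, "p_ev"); p_s <- num1(p_s, "p_s")
  q_conv <- num1(q_conv, "q_conv"); q_unc_hyd <- num1(q_unc_hyd, "q_unc_hyd")
  if (min(x_b, p_pc, p_ac, p_ev, p_s) <= 0)
    stop("all baseline pressures must be strictly positive")
  if (!(p_pc > x_b && x_b > p_ac && p_ac > p_ev))
    stop("baseline pressure cascade violated: need p_pc > x_b > p_ac > p_ev")
  if (!(p_ac > p_s))
    stop("baseline pressure cascade violated: need p_ac > p_s")
  if (q_conv <= 0 || q_unc_hyd <= 0)
    stop("baseline flows `q_conv` and `q_unc_hyd` must be strictly positive")
  if (is.null(q_total)) q_total <- q_conv + q_unc_hyd
  q_total <- num1(q_total, "q_total")
  if (q_total <= 0) stop("`q_total` must be strictly positive")
  structure(
    list(
      x_b = x_b, p_pc = p_pc, p_ac = p_ac, p_ev = p_ev, p_s = p_s,
      q_conv = convert_flow(q_conv, "uL/min", "m3/s"),
      q_unc_hyd = convert_flow(q_unc_hyd, "uL/min", "m3/s"),
      q_total = convert_flow(q_total, "uL/min", "m3/s")
    ),
    class = "aq_baseline"
  )
}

#' Topical drug regimen (prostaglandin analog, 1 drop/day)
#'
#' Describes a daily-drop therapy.  Only the cumulative absorbed mass enters
#' the model: after `day` drops it is `f_bio * m_onedrop * day` (no
#' intraocular pharmacokinetics; corneal absorption is summarised by the
#' bioavailability fraction).  Defaults correspond to latanoprost 0.005%
#' for 14 days: 5% bioavailability, 1.5625 ug per drop.
#'
#' @param f_bio bioavailability fraction in `[0, 1]`.
#' @param m_onedrop drug mass in one drop (ug).
#' @param n_days length of the therapy (days, 1 drop/day).
#' @return an object of class `aq_regimen` with the derived total absorbed
#'   mass `m_tot_abs = f_bio * m_onedrop * n_days` (ug).
#' @examples
#' drug_regimen()$m_tot_abs  # 1.09375 ug
#' @export
drug_regimen <- function(f_bio = 0.05, m_onedrop = 1.5625, n_days = 14L) {
  if (!is.numeric(f_bio) || length(f_bio) != 1L || f_bio < 0 || f_bio > 1)
    stop("`f_bio` must be a single number in [0, 1]")
  if (!is.numeric(m_onedrop) || length(m_onedrop) != 1L || m_onedrop <= 0)
    stop("`m_onedrop` must be a single positive number (ug)")
  if (!is.numeric(n_days) || length(n_days) != 1L || n_days < 0 ||
      n_days != round(n_days))
    stop("`n_days` must be a single non-negative integer")
  structure(
    list(f_bio = as.numeric(f_bio), m_onedrop = as.numeric(m_onedrop),
         n_days = as.integer(n_days),
         m_tot_abs = as.numeric(f_bio) * as.numeric(m_onedrop) * as.numeric(n_days)),
    class = "aq_regimen"
  )
}

#' Calibrate the hydraulic circuit from baseline physiology
#'
#' Applies the discrete Ohm/Darcy law `L = Q / dp` to the baseline record to
#' obtain the four conductances of the circuit, and assembles the Hill
#' parameter sets of the two unconventional-route nonlinearities:
#'
#' * `L_pc = Q_b / (p_pc - x_b)`, posterior chamber;
#' * `L_ac = Q_b / (x_b - p_ac)`, anterior chamber;
#' * `L_conv_b = Q_conv_b / (p_ac - p_ev)`, conventional (trabecular) route;
#' * `L_unc_b = Q_unc_hyd_b / (p_ac - p_s)`, unconventional route at baseline.
#'
#' Derived constants: `P_b = p_s + Q_b / L_ac` (the pressure the anterior
#' chamber node relaxes to when referenced to the suprachoroidal space) and
#' the normalisation `denom_Z = x_b - P_b` of the pressure-deviation variable.
#' The pressure-activated Hill set uses
#' `k_act_hyd = (p05 - x_b) / (x_b - P_b)` with `p05 = (x_b + iop_path)/2`
#' (halfway from healthy to conventionally pathological IOP), asymptote
#' `kappa_hyd * beta_max_hyd` (dimensionless conductance gain).  The
#' drug-activated set uses `k_act_drug = 0.5 * m_tot_abs` (half the total
#' absorbed mass of the full regimen) and asymptote
#' `kappa_drug * beta_max_drug` (m^3/s).
#'
#' @param baseline an [baseline_physiology()] record.
#' @param regimen a [drug_regimen()].
#' @param kappa_hyd gain on the pressure-dependent unconventional conductance
#'   (0 = linear resistor model, 0.99 = nonlinear reference, 10 = strongly
#'   saturating regime).
#' @param kappa_drug gain on the drug-dependent unconventional flow source.
#' @param beta_max_hyd maximal relative conductance increase of the
#'   pressure-dependent route (dimensionless).
#' @param beta_max_drug maximal drug-driven flow (m^3/s).
#' @param hill_p Hill exponent (integer >= 1; 4 throughout).
#' @param iop_path conventionally pathological IOP threshold (mmHg).
#' @return an object of class `aq_model` carrying the conductances,
#'   resistances, derived pressures, both Hill parameter sets, and the
#'   baseline/regimen records used.
#' @examples
#' m <- calibrate()
#' signif(m$L_pc, 3)      # 9.17e-11 m^3 s^-1 mmHg^-1
#' signif(m$denom_Z, 3)   # 3.63 mmHg
#' @export
calibrate <- function(baseline = baseline_physiology(),
                      regimen = drug_regimen(),
                      kappa_hyd = 0.99,
                      kappa_drug = 0.33,
                      beta_max_hyd = 0.1493,
                      beta_max_drug = 7.87e-11,
                      hill_p = 4L,
                      iop_path = 21) {
  stopifnot(inherits(baseline, "aq_baseline"), inherits(regimen, "aq_regimen"))
  if (kappa_hyd < 0 || kappa_drug < 0)
    stop("`kappa_hyd` and `kappa_drug` must be non-negative")
  if (beta_max_hyd < 0 || beta_max_drug < 0)
    stop("`beta_max_hyd` and `beta_max_drug` must be non-negative")
  if (hill_p < 1 || hill_p != round(hill_p))
    stop("`hill_p` must be an integer >= 1")

  drop_or_stop <- function(dp, what) {
    if (dp <= 0)
      stop(sprintf("calibration error: non-positive pressure drop across %s (baseline inconsistent)", what))
    dp
  }
  b <- baseline
  L_pc <- b$q_total / drop_or_stop(b$p_pc - b$x_b, "the posterior chamber")
  L_ac <- b$q_total / drop_or_stop(b$x_b - b$p_ac, "the anterior chamber")
  L_conv_b <- b$q_conv / drop_or_stop(b$p_ac - b$p_ev, "the conventional route")
  L_unc_b <- b$q_unc_hyd / drop_or_stop(b$p_ac - b$p_s, "the unconventional route")

  P_b <- b$p_s + b$q_total / L_ac
  denom_Z <- b$x_b - P_b
  if (denom_Z <= 0)
    stop("calibration error: x_b - P_b must be positive")
  p05 <- (b$x_b + iop_path) / 2
  k_act_hyd <- (p05 - b$x_b) / denom_Z
  if (k_act_hyd <= 0)
    stop("calibration error: `iop_path` must exceed the baseline IOP")
  if (regimen$m_tot_abs <= 0 && kappa_drug > 0)
    stop("calibration error: drug regimen has zero absorbed mass but kappa_drug > 0")
  k_act_drug <- 0.5 * regimen$m_tot_abs

  structure(
    list(
      L_pc = L_pc, L_ac = L_ac, L_conv_b = L_conv_b, L_unc_b = L_unc_b,
      R_ac_b = 1 / L_ac, R_conv_b = 1 / L_conv_b,
      P_b = P_b, denom_Z = denom_Z,
      hill_hyd = list(beta = kappa_hyd * beta_max_hyd, k_act = k_act_hyd,
                      p = as.integer(hill_p)),
      hill_drug = list(beta = kappa_drug * beta_max_drug,
                       k_act = if (k_act_drug > 0) k_act_drug else NA_real_,
                       p = as.integer(hill_p)),
      kappa_hyd = kappa_hyd, kappa_drug = kappa_drug,
      beta_max_hyd = beta_max_hyd, beta_max_drug = beta_max_drug,
      iop_path = iop_path,
      baseline = baseline, regimen = regimen
    ),
    class = "aq_model"
  )
}

# Re-run the calibration of `model` with different kappa gains, keeping the
# baseline record, regimen and all other knobs untouched.
.with_kappa <- function(model, kappa_hyd = NULL, kappa_drug = NULL) {
  calibrate(
    baseline = model$baseline, regimen = model$regimen,
    kappa_hyd = if (is.null(kappa_hyd)) model$kappa_hyd else kappa_hyd,
    kappa_drug = if (is.null(kappa_drug)) model$kappa_drug else kappa_drug,
    beta_max_hyd = model$beta_max_hyd, beta_max_drug = model$beta_max_drug,
    hill_p = model$hill_hyd$p, iop_path = model$iop_path
  )
}

#' @export
print.aq_model <- function(x, ...) {
  cat("Calibrated aqueous humor circuit model\n")
  cat(sprintf("  L_pc     = %.4g m^3 s^-1 mmHg^-1\n", x$L_pc))
  cat(sprintf("  L_ac     = %.4g m^3 s^-1 mmHg^-1\n", x$L_ac))
  cat(sprintf("  L_conv_b = %.4g m^3 s^-1 mmHg^-1\n", x$L_conv_b))
  cat(sprintf("  L_unc_b  = %.4g m^3 s^-1 mmHg^-1\n", x$L_unc_b))
  cat(sprintf("  P_b = %.4f mmHg, x_b - P_b = %.4f mmHg\n", x$P_b, x$denom_Z))
  cat(sprintf("  hill_hyd:  beta = %.4g, k_act = %.4g, p = %d\n",
              x$hill_hyd$beta, x$hill_hyd$k_act, x$hill_hyd$p))
  cat(sprintf("  hill_drug: beta = %.4g m^3/s, k_act = %.4g ug, p = %d\n",
              x$hill_drug$beta, x$hill_drug$k_act, x$hill_drug$p))
  invisible(x)
}
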