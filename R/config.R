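#' Default run configuration
#'
#' The full configuration of a run as a nested list whose defaults are the
#' reference physiology and regimen; every field can be overridden from a
#' JSON file.  Pressures in mmHg (`baseline$p_ac_pa` may be used instead of
#' `baseline$p_ac` to give the anterior chamber pressure in Pa), flows in
#' uL/min, drug masses in ug.
#'
#' @return a named nested list (class `aq_config`).
#' @export
default_config <- function() {
  structure(list(
    baseline = list(
      x_b = 15, p_pc = 15.5, p_ac = convert_pressure(1950, "Pa", "mmHg"),
      p_ev = 8, p_s = 11,
      q_conv_ul_min = 2.45, q_unc_hyd_ul_min = 0.3,
      q_total_ul_min = NULL
    ),
    regimen = list(f_bio = 0.05, m_onedrop_ug = 1.5625, n_days = 14),
    kappa_hyd = 0.99,
    kappa_drug = 0.33,
    beta_max_hyd = 0.1493,
    beta_max_drug = 7.87e-11,
    hill_p = 4,
    iop_path = 21,
    solver = list(rel_tol = 1e-11, max_iter = 100, x0 = NULL, bracket = c(11, 60))
  ), class = "aq_config")
}

# Merge user overrides into the defaults, rejecting unknown keys.
.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop(sprintf("config section `%s` must be an object", path))
  unknown <- setdiff(names(user), names(defaults))
  if (path == "baseline") unknown <- setdiff(unknown, "p_ac_pa")
  if (length(unknown))
    stop(sprintf("unknown configuration key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste0(if (nzchar(path)) paste0(path, "$") else "",
                        unknown, collapse = ", ")))
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, "$", k) else k
    if (k %in% c("baseline", "regimen", "solver")) {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]], k)
    } else {
      v <- user[[k]]
      if (!is.null(v) && !is.numeric(v))
        stop(sprintf("configuration key `%s` must be numeric", full))
      defaults[[k]] <- if (is.null(v)) NULL else as.numeric(v)
    }
  }
  defaults
}

#' Load a run configuration from a JSON file
#'
#' Reads a (possibly empty) JSON object, fills every missing field with the
#' default value from [default_config()], rejects unknown keys, and
#' validates the result by building the model once.
#'
#' @param path path to a JSON file; an empty object `{}` (or an empty file)
#'   yields the full default configuration.
#' @return an `aq_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (!nzchar(trimws(txt))) list() else
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  cfg <- .merge_config(default_config(), user)
  if (!is.null(cfg$baseline$p_ac_pa)) {
    cfg$baseline$p_ac <- convert_pressure(cfg$baseline$p_ac_pa, "Pa", "mmHg")
    cfg$baseline$p_ac_pa <- NULL
  }
  class(cfg) <- "aq_config"
  build_model(cfg)  # validation: invariant breaches surface here
  cfg
}

#' Build the calibrated model described by a configuration
#'
#' @param cfg an `aq_config` (see [default_config()], [load_config()]).
#' @return an `aq_model`, see [calibrate()].
#' @export
build_model <- function(cfg) {
  b <- cfg$baseline
  baseline <- baseline_physiology(
    x_b = b$x_b, p_pc = b$p_pc, p_ac = b$p_ac, p_ev = b$p_ev, p_s = b$p_s,
    q_conv = b$q_conv_ul_min, q_unc_hyd = b$q_unc_hyd_ul_min,
    q_total = b$q_total_ul_min
  )
  regimen <- drug_regimen(f_bio = cfg$regimen$f_bio,
                          m_onedrop = cfg$regimen$m_onedrop_ug,
                          n_days = cfg$regimen$n_days)
  calibrate(baseline, regimen,
            kappa_hyd = cfg$kappa_hyd, kappa_drug = cfg$kappa_drug,
            beta_max_hyd = cfg$beta_max_hyd, beta_max_drug = cfg$beta_max_drug,
            hill_p = cfg$hill_p, iop_path = cfg$iop_path)
}

#' Build the solver configuration described by a configuration
#'
#' @param cfg an `aq_config`.
#' @param model the matching `aq_model` (defaults are taken from it).
#' @return an [solver_config()].
#' @export
build_solver_config <- function(cfg, model = build_model(cfg)) {
  s <- cfg$solver
  solver_config(model, rel_tol = s$rel_tol, max_iter = s$max_iter,
                x0 = if (is.null(s$x0)) model$baseline$x_b else s$x0,
                bracket = s$bracket)
}
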