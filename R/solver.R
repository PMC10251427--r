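#' Solver settings
#'
#' @param model the [calibrate()]d model the defaults are taken from.
#' @param rel_tol relative stopping tolerance on successive iterates
#'   (`|x_{k+1} - x_k| / x_{k+1} <= rel_tol`).
#' @param max_iter maximum number of fixed-point iterations.
#' @param x0 initial IOP guess (mmHg); defaults to the baseline IOP.
#' @param bracket physical search interval (mmHg) for the root-finding oracle
#'   and the contraction diagnostic; defaults to `[p_s, 60]`, whose upper end
#'   safely exceeds any simulated IOP.
#' @return an object of class `aq_solver_config`.
#' @export
solver_config <- function(model = calibrate(), rel_tol = 1e-11,
                          max_iter = 100L, x0 = model$baseline$x_b,
                          bracket = c(model$baseline$p_s, 60)) {
  if (!is.numeric(rel_tol) || length(rel_tol) != 1L || rel_tol <= 0)
    stop("`rel_tol` must be a single positive number")
  if (max_iter < 1) stop("`max_iter` must be >= 1")
  if (length(bracket) != 2L || bracket[1] >= bracket[2])
    stop("`bracket` must be an increasing pressure interval (mmHg)")
  if (x0 < bracket[1] || x0 > bracket[2])
    stop("`x0` must lie inside `bracket`")
  structure(list(rel_tol = as.numeric(rel_tol), max_iter = as.integer(max_iter),
                 x0 = as.numeric(x0), bracket = as.numeric(bracket)),
            class = "aq_solver_config")
}

#' Solve a scenario by fixed-point (Picard) iteration
#'
#' Iterates `x <- T_m(x)` from `config$x0` until the relative update falls
#' below `config$rel_tol`.  When the pressure-dependent nonlinearity is off
#' (`kappa_hyd = 0`) the map is constant in `x` and the fixed point is taken
#' in closed form (`method = "closed_form_linear"`, one map evaluation) —
#' this is why linear-model sweeps conserve mass to machine precision while
#' nonlinear ones inherit the iteration tolerance.
#'
#' Strongly saturating regimes (large `kappa_hyd`) can place the fixed point
#' where `|dT_m/dx| >= 1`; there the Picard iteration genuinely diverges even
#' though the steady state exists as the bracketed root of `x - T_m(x)`.
#' `on_failure = "bracket"` falls back to [solve_root_oracle()] in that case
#' (`method = "bracketed_root"`); the default (`"error"`) signals a
#' diagnostic-bearing error instead.
#'
#' @param scen an [scenario()].
#' @param config an [solver_config()]; `NULL` uses defaults for the
#'   scenario's model.
#' @param on_failure what to do when `max_iter` is exhausted: `"error"`
#'   (default) signals an error of class `aq_nonconvergence` whose condition
#'   carries the last iterate (`$last_x`) and the [contraction_check()]
#'   diagnostic (`$diagnostic`); `"bracket"` solves by bracketed root-finding
#'   instead.
#' @return the converged [recover_state()] (class `aq_state`).
#' @examples
#' m <- calibrate()
#' solve_fixed_point(scenario(m, eta = 1))$x       # 15 mmHg (baseline)
#' @export
solve_fixed_point <- function(scen, config = NULL,
                              on_failure = c("error", "bracket")) {
  stopifnot(inherits(scen, "aq_scenario"))
  on_failure <- match.arg(on_failure)
  if (is.null(config)) config <- solver_config(scen$model)
  consts <- map_constants(scen)

  if (scen$model$hill_hyd$beta == 0) {
    # T_m constant in x: evaluate once, exactly
    x <- iteration_map(config$x0, scen, consts)
    return(recover_state(x, scen, iterations = 1L,
                         method = "closed_form_linear"))
  }

  x <- config$x0
  for (k in seq_len(config$max_iter)) {
    x_new <- iteration_map(x, scen, consts)
    if (abs(x_new - x) / abs(x_new) <= config$rel_tol)
      return(recover_state(x_new, scen, iterations = k,
                           method = "fixed_point"))
    x <- x_new
  }
  if (on_failure == "bracket") {
    root <- solve_root_oracle(scen, config)
    return(recover_state(root, scen, iterations = config$max_iter,
                         method = "bracketed_root"))
  }
  diag <- contraction_check(scen, config$bracket)
  cond <- structure(
    class = c("aq_nonconvergence", "error", "condition"),
    list(message = sprintf(
           paste0("fixed-point iteration did not converge in %d iterations ",
                  "(last x = %.6f mmHg, sup |T'| over bracket = %.4g%s)"),
           config$max_iter, x, diag$sup_abs_derivative,
           if (diag$is_contraction) "" else "; map is not a contraction there"),
         call = sys.call(-1), last_x = x, diagnostic = diag)
  )
  stop(cond)
}

#' Independent bracketed root-finding oracle
#'
#' Solves the same steady state as [solve_fixed_point()] but as the bracketed
#' root of the residual `f(x) = x - T_m(x)` via [stats::uniroot()] (Brent's
#' safeguarded interpolation), providing a verification route that does not
#' rely on the contraction property of the map.
#'
#' @param scen an [scenario()].
#' @param config an [solver_config()]; only the bracket is used.
#' @return the root (IOP, mmHg).
#' @export
solve_root_oracle <- function(scen, config = NULL) {
  stopifnot(inherits(scen, "aq_scenario"))
  if (is.null(config)) config <- solver_config(scen$model)
  consts <- map_constants(scen)
  f <- function(x) x - iteration_map(x, scen, consts)
  lo <- f(config$bracket[1]); hi <- f(config$bracket[2])
  if (is.na(lo) || is.na(hi) || sign(lo) == sign(hi))
    stop("residual does not change sign on the bracket; scenario out of range")
  stats::uniroot(f, interval = config$bracket, tol = 1e-13,
                 maxiter = 1000L)$root
}

#' Numerical contraction diagnostic of the iteration map
#'
#' Estimates `sup |dT_m/dx|` over a bracket by dense central differences.  A
#' value below 1 certifies (numerically) that the Picard iteration contracts
#' on the bracket; strongly saturating regimes (large `kappa_hyd`) can exceed
#' 1 locally yet still converge in practice.
#'
#' @param scen an [scenario()].
#' @param bracket pressure interval (mmHg); defaults to the model's solver
#'   default `[p_s, 60]`.
#' @param n number of grid points (default 2001).
#' @return list with `sup_abs_derivative` and logical `is_contraction`.
#' @export
contraction_check <- function(scen, bracket = NULL, n = 2001L) {
  stopifnot(inherits(scen, "aq_scenario"))
  if (is.null(bracket)) bracket <- c(scen$model$baseline$p_s, 60)
  if (length(bracket) != 2L || bracket[1] >= bracket[2])
    stop("`bracket` must be an increasing pressure interval (mmHg)")
  consts <- map_constants(scen)
  xs <- seq(bracket[1], bracket[2], length.out = n)
  h <- (bracket[2] - bracket[1]) / (n - 1)
  tx <- iteration_map(xs, scen, consts)
  d <- abs(tx[-1] - tx[-length(tx)]) / h  # one-sided on the grid = central on midpoints
  sup <- max(d)
  list(sup_abs_derivative = sup, is_contraction = sup < 1)
}
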