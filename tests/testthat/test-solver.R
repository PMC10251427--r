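test_that("baseline scenario solves to the baseline IOP", {
  m <- default_model()
  st <- solve_fixed_point(scenario(m, eta = 1))
  expect_equal(st$x, 15, tolerance = 1e-10)
  expect_lt(abs(st$residual), 1e-9)
  expect_identical(st$method, "fixed_point")
})

test_that("linear regime is solved in closed form, matching the oracle", {
  lin <- default_model(kappa_hyd = 0)
  st <- solve_fixed_point(scenario(lin, eta = 3))
  expect_identical(st$method, "closed_form_linear")
  expect_identical(st$iterations, 1L)
  expect_equal(st$x, oracle_linear_iop(3), tolerance = 1e-13)
  expect_equal(st$residual, 0)
  # with drug
  st14 <- solve_fixed_point(scenario(lin, eta = 3, m_abs = 1.09375))
  expect_equal(st14$x, oracle_linear_iop(3, m_abs = 1.09375), tolerance = 1e-13)
})

test_that("fixed point and bracketed-root oracle agree over the scenario grid", {
  # In the protocol regimes (kappa_hyd 0 and 0.99) the Picard route and the
  # bracketed-root route are genuinely independent and must agree.  At
  # kappa_hyd = 10 the fixed point can sit where |T'| >= 1 (Picard diverges),
  # so the bracket fallback may engage there -- but never in the protocol
  # regimes.
  regimen <- drug_regimen()
  grid <- expand.grid(eta = c(1, 1.5, 2, 2.5, 3),
                      kappa = c(0, 0.99, 10),
                      day = c(0, 7, 14))
  for (i in seq_len(nrow(grid))) {
    m <- default_model(kappa_hyd = grid$kappa[i])
    sc <- scenario(m, eta = grid$eta[i],
                   m_abs = absorbed_mass(grid$day[i], regimen))
    st <- solve_fixed_point(sc, on_failure = "bracket")
    root <- solve_root_oracle(sc)
    expect_lt(abs(st$x - root), 1e-8)
    # conservation at every converged solution
    expect_lt(abs(st$Q_conv + st$Q_unc - m$baseline$q_total) /
                m$baseline$q_total, 1e-9)
    # full KCL residuals vanish at the fixed point
    expect_equal(st$Q12, m$baseline$q_total)
    expect_equal(st$Q23, m$baseline$q_total)
    if (grid$kappa[i] %in% c(0, 0.99)) {
      # iteration bound and dual-route integrity in the protocol regimes
      expect_lte(st$iterations, 26L)
      expect_false(st$method == "bracketed_root")
    }
  }
})

test_that("Picard genuinely diverges where |T'| >= 1 (kappa_hyd = 10, day 7)", {
  m <- default_model(kappa_hyd = 10)
  sc <- scenario(m, eta = 3, m_abs = absorbed_mass(7, m$regimen))
  err <- tryCatch(solve_fixed_point(sc), aq_nonconvergence = function(e) e)
  expect_s3_class(err, "aq_nonconvergence")
  expect_false(err$diagnostic$is_contraction)
  # the steady state still exists and is found by the bracket fallback
  st <- solve_fixed_point(sc, on_failure = "bracket")
  expect_identical(st$method, "bracketed_root")
  expect_lt(abs(st$x - solve_root_oracle(sc)), 1e-10)
})

test_that("solved IOP is monotone in resistance and in drug mass", {
  m <- default_model()
  x_eta <- vapply(seq(1, 3, by = 0.25), function(e)
    solve_fixed_point(scenario(m, eta = e))$x, numeric(1))
  expect_true(all(diff(x_eta) > 0))
  x_day <- vapply(absorbed_mass(0:14, m$regimen), function(mm)
    solve_fixed_point(scenario(m, eta = 3, m_abs = mm))$x, numeric(1))
  expect_true(all(diff(x_day) <= 0))
})

test_that("contraction diagnostic reflects the kappa regime", {
  lin <- default_model(kappa_hyd = 0)
  expect_identical(contraction_check(scenario(lin, eta = 3))$sup_abs_derivative, 0)
  nl <- contraction_check(scenario(default_model(), eta = 3))
  expect_true(nl$is_contraction)
  expect_gt(nl$sup_abs_derivative, 0)
  # strongly saturating regime: diagnostic is finite and reported even though
  # the map can fail the sufficient contraction bound locally
  strong <- contraction_check(scenario(default_model(kappa_hyd = 10), eta = 3))
  expect_true(is.finite(strong$sup_abs_derivative))
})

test_that("non-convergence raises a diagnostic-bearing error", {
  m <- default_model(kappa_hyd = 10)
  sc <- scenario(m, eta = 3)
  cfg <- solver_config(m, max_iter = 2L)
  err <- tryCatch(solve_fixed_point(sc, cfg), aq_nonconvergence = function(e) e)
  expect_s3_class(err, "aq_nonconvergence")
  expect_true(is.finite(err$last_x))
  expect_true(is.list(err$diagnostic))
  expect_true(is.finite(err$diagnostic$sup_abs_derivative))
})

test_that("root oracle refuses a bracket without sign change", {
  m <- default_model()
  cfg <- solver_config(m, x0 = 40, bracket = c(30, 60))
  expect_error(solve_root_oracle(scenario(m, eta = 1), cfg), "sign")
})

test_that("solver configuration is validated", {
  m <- default_model()
  expect_error(solver_config(m, rel_tol = 0), "positive")
  expect_error(solver_config(m, bracket = c(60, 11)), "increasing")
  expect_error(solver_config(m, x0 = 5), "inside")
})
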