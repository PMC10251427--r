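test_that("Hill function hits its exact landmarks and saturates safely", {
  prm <- list(beta = 2.5, k_act = 0.7, p = 4L)
  expect_identical(hill(0, prm), 0)
  expect_equal(hill(0.7, prm), 2.5 / 2)
  expect_equal(hill(1.4, prm), 2.5 * 16 / 17)  # (2K)^4/((2K)^4+K^4) = 16/17
  expect_equal(hill(1e200, prm), 2.5)          # no overflow at extreme xi
  # monotone nondecreasing and bounded by beta on a dense grid
  xi <- seq(0, 10, length.out = 500)
  v <- hill(xi, prm)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v <= 2.5))
  expect_error(hill(-0.1, prm), "non-negative")
  expect_identical(hill(c(1, 2), list(beta = 0, k_act = 1, p = 4L)), c(0, 0))
})

test_that("pressure deviation Z(x) is clamped below baseline and linear above", {
  m <- default_model()
  expect_identical(z_of_x(15, m), 0)
  expect_identical(z_of_x(10, m), 0)
  expect_equal(z_of_x(22.3, m), 7.3 / (1950 / 133.322 - 11))  # ~2.013
  xs <- seq(10, 30, by = 0.25)
  expect_true(all(diff(z_of_x(xs, m)) >= 0))
})

test_that("unconventional conductance and drug source follow their Hill laws", {
  m <- default_model()
  expect_equal(l_unc_hyd(0, m), m$L_unc_b)
  lin <- default_model(kappa_hyd = 0)
  expect_equal(l_unc_hyd(c(0, 1, 5), lin), rep(lin$L_unc_b, 3))
  expect_equal(l_unc_hyd(m$hill_hyd$k_act, m),
               m$L_unc_b * (1 + 0.99 * 0.1493 / 2))
  expect_lte(max(l_unc_hyd(seq(0, 100, 0.5), m)),
             m$L_unc_b * (1 + m$hill_hyd$beta))

  expect_identical(q_unc_drug(0, m), 0)
  expect_equal(q_unc_drug(m$hill_drug$k_act, m), m$hill_drug$beta / 2)
  # full regimen mass is exactly 2 * k_act, hence 16/17 of the asymptote
  expect_equal(q_unc_drug(m$regimen$m_tot_abs, m), m$hill_drug$beta * 16 / 17)
  expect_identical(q_unc_drug(5, default_model(kappa_drug = 0)), 0)
})

test_that("absorbed mass is cumulative and exact", {
  r <- drug_regimen()
  expect_identical(absorbed_mass(0, r), 0)
  expect_equal(absorbed_mass(14, r), 1.09375)
  expect_equal(absorbed_mass(7, r), 0.546875)  # half-maximum after one week
  expect_equal(absorbed_mass(0:14, r), 0.078125 * (0:14))
  expect_error(absorbed_mass(-1, r), "non-negative")
  expect_error(absorbed_mass(1.5, r), "integer")
})

test_that("iteration map has the baseline as exact fixed point", {
  m <- default_model()
  expect_equal(iteration_map(15, scenario(m, eta = 1)), 15)
  # linear regime: map constant in x, equal to the independent closed form
  lin <- default_model(kappa_hyd = 0)
  sc3 <- scenario(lin, eta = 3)
  xs <- c(12, 15, 20, 25, 40)
  tv <- iteration_map(xs, sc3)
  expect_equal(tv, rep(tv[1], length(xs)))
  expect_equal(tv[1], oracle_linear_iop(3), tolerance = 1e-12)
  # increasing drug mass strictly decreases the map at fixed x
  t_m <- vapply(c(0, 0.25, 0.5, 1), function(mm)
    iteration_map(20, scenario(m, eta = 3, m_abs = mm)), numeric(1))
  expect_true(all(diff(t_m) < 0))
})

test_that("recover_state back-substitutes the baseline circuit", {
  m <- default_model()
  st <- recover_state(15, scenario(m, eta = 1), iterations = 1L,
                      method = "fixed_point")
  expect_equal(st$z, 15.5)
  expect_equal(st$y, m$baseline$p_ac)
  expect_equal(convert_flow(st$Q_conv, "m3/s", "uL/min"), 2.45)
  expect_equal(convert_flow(st$Q_unc_hyd, "m3/s", "uL/min"), 0.3)
  expect_equal(st$Q12, st$Q23)
  expect_equal(st$Q_conv + st$Q_unc, m$baseline$q_total)
  expect_equal(st$residual, 0)
})

test_that("scenario and map constants validate and expose the circuit scaling", {
  m <- default_model()
  expect_error(scenario(m, eta = 0), "positive")
  expect_error(scenario(m, m_abs = -1), "non-negative")
  cs <- map_constants(scenario(m, eta = 3))
  expect_equal(cs$R_conv, 3 * m$R_conv_b)
  expect_equal(cs$R_tot, cs$R_conv + m$R_ac_b)
  expect_equal(cs$P_tilde, m$baseline$p_ev + cs$R_tot * m$baseline$q_total)
  expect_identical(cs$phi_tilde, 0)
  expect_gt(map_constants(scenario(m, eta = 3, m_abs = 1))$phi_tilde, 0)
})
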