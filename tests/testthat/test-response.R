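test_that("hill_fit recovers exact Hill curves and is scale-equivariant", {
  cc <- concentration_grid()
  a <- 0.5 / (1 + (cc / 0.1)^2)
  h <- hill_fit(cc, a)
  expect_true(h$converged)
  expect_equal(h$amplitude, 0.5, tolerance = 1e-8)
  expect_equal(h$c_half, 0.1, tolerance = 1e-8)
  expect_equal(h$n_hill, 2, tolerance = 1e-8)
  expect_lt(h$rss, 1e-16)

  # scaling the curve scales the amplitude only
  h3 <- hill_fit(cc, 3 * a)
  expect_equal(h3$amplitude, 1.5, tolerance = 1e-8)
  expect_equal(h3$c_half, h$c_half, tolerance = 1e-8)
  expect_equal(h3$n_hill, h$n_hill, tolerance = 1e-8)

  expect_error(hill_fit(cc[1:3], a[1:3]), "4 points")
  expect_error(hill_fit(cc, rep(0, length(cc))), "all-zero")
})

test_that("hill_fit recovers the coefficient from noisy curves", {
  # 1% additive noise; the estimate must stay within 3x its sampling
  # spread, estimated from replicate noise realizations
  cc <- concentration_grid()
  truth <- 0.5 / (1 + (cc / 0.05)^3)
  set.seed(404)
  n_rep <- vapply(1:40, function(k)
    hill_fit(cc, truth + stats::rnorm(length(cc), 0, 0.005))$n_hill,
    numeric(1))
  expect_lt(abs(mean(n_rep) - 3), 3 * stats::sd(n_rep))
  expect_lt(abs(n_rep[1] - 3), 3 * stats::sd(n_rep))
})

test_that("classical MWC activity matches hand evaluation and its Hill limit", {
  # at zero ligand and zero offset the two states are equally likely
  expect_equal(classical_mwc_activity(0, n = 3, delta_eps = 0,
                                      kd_on = 0.5, kd_off = 0.02), 0.5)
  # hand evaluation
  expect_equal(
    classical_mwc_activity(0.1, n = 6, delta_eps = -1, kd_on = 0.5,
                           kd_off = 0.02),
    1 / (1 + exp(6 * (-1 + log((1 + 0.1 / 0.02) / (1 + 0.1 / 0.5))))),
    tolerance = 1e-12
  )
  expect_equal(round(classical_mwc_activity(0.1, 6, -1, 0.5, 0.02), 4),
               0.0252)
  expect_error(classical_mwc_activity(0.1, 0, -1, 0.5, 0.02), "n must be")

  # for kd_off << c << kd_on the fitted Hill coefficient approaches the
  # complex size N (checked at a contrast of 1e4 between the constants)
  # delta_eps places c_H well inside (kd_off, kd_on)
  n_true <- 6
  cc <- concentration_grid(50, 1e-3, 1)
  act <- classical_mwc_activity(cc, n_true, delta_eps = -4, kd_on = 10,
                                kd_off = 1e-3)
  h <- hill_fit(cc, act)
  expect_equal(h$n_hill, n_true, tolerance = 0.05)
})

test_that("dose-response modes and error paths behave", {
  p <- fig_expression_params()
  expect_error(dose_response(p, grid = c(0.1, 0.1)), "strictly increasing")
  expect_error(dose_response(p, grid = concentration_grid(5),
                             mode = "constant_mu"), "requires mu")

  # without CheA the curve is identically zero and cannot be Hill-fitted.
  # CheA-free complexes are single trimers, so the density target must be
  # attainable with 3 dimers per occupied site
  p2 <- ensemble_parameters(p$delta_eps, p$kd_on, p$kd_off, p$j_coupling,
                            p$mu_w0, p$mu_a2_0, rho = 2)
  dr0 <- dose_response(p2, expression_condition(1, 0), concentration_grid(8))
  expect_true(all(dr0$activity == 0))
  expect_error(hill_fit(dr0), "all-zero")
  # an unattainable density with no CheA fails with diagnostics
  expect_error(dose_response(p, expression_condition(1, 0),
                             concentration_grid(5)), "not bracketable")
})

test_that("a 1x1 expression scan equals the direct dose-response fit", {
  p <- fig_expression_params()
  grid <- concentration_grid(30)
  tab <- scan_expression(p, 1, 1, grid)
  h <- hill_fit(dose_response(p, expression_condition(1, 1), grid))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$amplitude, h$amplitude, tolerance = 1e-10)
  expect_equal(tab$c_half, h$c_half, tolerance = 1e-10)
  expect_equal(tab$n_hill, h$n_hill, tolerance = 1e-10)
})

test_that("amplitude grows with CheA along a scan row", {
  p <- fig_wonly_params("W")
  tab <- scan_expression(p, 1, c(0.25, 1, 4, 16), concentration_grid(25))
  expect_true(all(diff(tab$amplitude) > 0))
})

test_that("CheA-per-linker ratio is 1 for bridged linkers and drops with CheW", {
  p <- fig_expression_params()
  st <- ensemble_state(p, expression_condition(1, 1), c = 0.01, mu = 0)
  expect_equal(chea_per_linker(st), 1)

  pw <- fig_wonly_params("W")
  ratio_at <- function(i) {
    sol <- solve_mu(pw, expression_condition(i, 1), c = 0.01)
    chea_per_linker(sol$state)
  }
  r1 <- ratio_at(1); r10 <- ratio_at(10)
  expect_true(r1 > 0 && r1 < 1)
  # extra CheW forms CheW-only linkers that exclude CheA
  expect_lt(r10, r1)

  # with the CheW2 unit priced out the ratio returns to 1
  pw_off <- ensemble_parameters(pw$delta_eps, pw$kd_on, pw$kd_off,
                                pw$j_coupling, pw$mu_w0, pw$mu_a2_0,
                                mu_w2_0 = 500, rho = pw$rho,
                                scheme = "bridged_wonly")
  st_off <- ensemble_state(pw_off, expression_condition(1, 1), c = 0.01,
                           mu = 0)
  expect_equal(chea_per_linker(st_off), 1, tolerance = 1e-10)

  # a single isolated trimer has no linkers at all
  p1 <- ensemble_parameters(p$delta_eps, p$kd_on, p$kd_off, p$j_coupling,
                            p$mu_w0, p$mu_a2_0, rho = 1.5, x_max = 1)
  st1 <- ensemble_state(p1, expression_condition(1, 1), c = 0.01, mu = 0)
  expect_error(chea_per_linker(st1), "undefined")
})
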