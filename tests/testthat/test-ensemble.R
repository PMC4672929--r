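test_that("single-dimer free energies follow the two-state form", {
  # at c = 0 the binding terms vanish
  f0 <- dimer_free_energies(0, delta_eps = -2.42, kd_on = 2.18,
                            kd_off = 0.002, mu = 0)
  expect_equal(f0$f_on, -2.42)
  expect_equal(f0$f_off, 0)

  # hand evaluation at c = 0.1 mM with the Tar QEQE offsets
  f <- dimer_free_energies(0.1, delta_eps = -1.12, kd_on = 2.18,
                           kd_off = 0.001, mu = 0)
  expect_equal(f$f_on, -1.12 - log(1 + 0.1 / 2.18), tolerance = 1e-12)
  expect_equal(f$f_on, -1.1649, tolerance = 1e-4)
  expect_equal(f$f_off, -log(101), tolerance = 1e-12)
  expect_equal(f$f_off, -4.6151, tolerance = 1e-4)

  # saturating ligand: the on/off gap approaches delta_eps + log(kon/koff)
  fs <- dimer_free_energies(1e12, delta_eps = -1.12, kd_on = 2.18,
                            kd_off = 0.001, mu = 0)
  expect_equal(fs$f_on - fs$f_off, -1.12 + log(2.18 / 0.001),
               tolerance = 1e-6)

  expect_error(dimer_free_energies(-1, -1, 2, 0.001), "nonnegative")
})

test_that("linker potentials scale logarithmically with expression level", {
  p <- fig_expression_params()
  wt <- linker_potentials(expression_condition(1, 1), p)
  expect_equal(wt$mu_w, p$mu_w0)
  expect_equal(wt$mu_a2, p$mu_a2_0)

  expect_equal(linker_potentials(expression_condition(10, 1), p)$mu_w,
               -0.67 - log(10), tolerance = 1e-12)
  expect_equal(linker_potentials(expression_condition(1, 0.25), p)$mu_a2,
               -1.68 - log(0.25), tolerance = 1e-12)

  # CheW2 carries two CheW monomers, so its potential scales twice as fast
  pw <- fig_wonly_params()
  expect_equal(linker_potentials(expression_condition(10, 1), pw)$mu_w2,
               pw$mu_w2_0 - 2 * log(10), tolerance = 1e-12)

  # no-CheA limit
  expect_equal(linker_potentials(expression_condition(1, 0), p)$mu_a2, Inf)
})

test_that("the zero-energy ensemble reduces to counting species", {
  # with every energy zero each of the 12 species has weight 2 (on + off),
  # so Z = 25 including the empty site
  st <- ensemble_state(zero_energy_params(), c = 0, mu = 0)
  expect_equal(st$p_empty, 1 / 25, tolerance = 1e-14)
  expect_equal(st$p_species, rep(2 / 25, 12), tolerance = 1e-14)
  expect_equal(st$p_on, rep(1 / 2, 12), tolerance = 1e-14)
  expect_equal(st$rho, 7.2, tolerance = 1e-12)
  # total CheA2 over species: 6 in linkers (R1) + 6 (R2) + 24 with full
  # rest groups, each active half the time
  expect_equal(st$activity, 36 / 25, tolerance = 1e-12)
})

test_that("probabilities normalize and match the naive-exponential oracle", {
  set.seed(101)
  for (rep in 1:25) {
    scheme <- sample(linker_schemes(), 1)
    p <- random_params(scheme)
    cond <- random_condition()
    c <- 10^stats::runif(1, -3.5, 0.5)
    mu <- stats::runif(1, -4, 4)

    st <- ensemble_state(p, cond, c, mu)
    expect_equal(sum(st$p_species) + st$p_empty, 1, tolerance = 1e-12)
    expect_true(all(st$p_on >= 0 & st$p_on <= 1))
    expect_true(st$activity >= 0)
    expect_true(st$rho >= 0 && st$rho <= 3 * p$x_max)

    # log-space path equals naive exponentials where the latter are finite
    or <- naive_ensemble(p, cond, c, mu)
    expect_equal(st$p_species, or$p_species, tolerance = 1e-10)
    expect_equal(st$p_empty, or$p_empty, tolerance = 1e-10)
    expect_equal(st$p_on, or$p_on, tolerance = 1e-10)
    expect_equal(st$activity, or$activity, tolerance = 1e-10)
  }
})

test_that("mixed-linker sums factorize over independent linker slots", {
  # each of the x - 1 slots independently holds a bridged or a CheW-only
  # linker, so summing compositions with binomial multiplicity must equal
  # the per-slot factor raised to x - 1
  set.seed(202)
  for (rep in 1:10) {
    p <- random_params("bridged_wonly")
    cond <- random_condition()
    c <- 10^stats::runif(1, -3, 0)
    mu <- stats::runif(1, -2, 2)
    st <- ensemble_state(p, cond, c, mu)

    pot <- linker_potentials(cond, p)
    f <- dimer_free_energies(c, p$delta_eps, p$kd_on, p$kd_off, mu)
    e_a <- pot$mu_a2 + 2 * pot$mu_w
    e_w <- pot$mu_w2 + 2 * pot$mu_w
    for (x in 1:p$x_max) for (rest in c("R1", "R2", "R3")) {
      rest_e <- switch(rest, R1 = 0, R2 = (x + 2) * pot$mu_w,
                       R3 = (x + 2) * (pot$mu_w + pot$mu_a2))
      closed <- exp(-3 * x * f$f_on - rest_e) *
        (exp(-(e_a + p$j_coupling)) + exp(-(e_w + p$j_coupling)))^(x - 1) +
        exp(-3 * x * f$f_off - rest_e) * (exp(-e_a) + exp(-e_w))^(x - 1)

      rows <- st$species$x == x & st$species$rest == rest
      z_rel <- sum(st$p_species[rows]) / st$p_empty  # = weight sum / 1
      expect_equal(z_rel, closed, tolerance = 1e-10 * max(1, abs(closed)))
    }
  }
})

test_that("CheW-only variants reduce to the base scheme as mu_w2 diverges", {
  p_base <- fig_expression_params()
  p_wonly <- ensemble_parameters(
    p_base$delta_eps, p_base$kd_on, p_base$kd_off, p_base$j_coupling,
    p_base$mu_w0, p_base$mu_a2_0, mu_w2_0 = 400, rho = p_base$rho,
    scheme = "bridged_wonly"
  )
  cond <- expression_condition(2, 0.5)
  for (c in c(0.003, 0.05, 0.8)) {
    a <- ensemble_state(p_base, cond, c, mu = 0.7)
    b <- ensemble_state(p_wonly, cond, c, mu = 0.7)
    expect_equal(b$rho, a$rho, tolerance = 1e-10)
    expect_equal(b$activity, a$activity, tolerance = 1e-10)
  }
})

test_that("without CheA the ensemble carries no activity", {
  p <- fig_expression_params()
  st <- ensemble_state(p, expression_condition(1, 0), c = 0.01, mu = 0)
  expect_equal(st$activity, 0)
  # species containing CheA2 have zero probability; CheA-free ones survive
  expect_true(all(st$p_species[st$species$n_a2 > 0] == 0))
  expect_true(sum(st$p_species) > 0)
  expect_equal(sum(st$p_species) + st$p_empty, 1, tolerance = 1e-12)
})
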