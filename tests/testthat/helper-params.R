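# Shared fixtures: published parameter sets and random parameter draws.

fig_expression_params <- function() caption_parameters("expression_series")
fig_tar_params <- function(mod = "QEQE") caption_parameters("tar_modification", mod)
fig_wonly_params <- function(family = "W") caption_parameters("wonly_series",
                                                              family = family)

# a parameter set with every energy zero: the ensemble reduces to counting
# (Z = 1 + 2 * n_species at c = 0, mu = 0)
zero_energy_params <- function(x_max = 4L, scheme = "bridged",
                               rho = 7.2, mu_w2_0 = 0) {
  ensemble_parameters(delta_eps = 0, kd_on = 2.18, kd_off = 0.002,
                      j_coupling = 0, mu_w0 = 0, mu_a2_0 = 0,
                      mu_w2_0 = mu_w2_0, rho = rho, x_max = x_max,
                      scheme = scheme)
}

random_params <- function(scheme = "bridged") {
  kd_off <- stats::runif(1, 1e-3, 0.05)
  ensemble_parameters(
    delta_eps = stats::runif(1, -3, 0),
    kd_on = kd_off * stats::runif(1, 50, 5000), kd_off = kd_off,
    j_coupling = stats::runif(1, -5, 0),
    mu_w0 = stats::runif(1, -2, 1), mu_a2_0 = stats::runif(1, -2, 1),
    mu_w2_0 = stats::runif(1, -6, 0),
    rho = stats::runif(1, 0.5, 10), scheme = scheme
  )
}

random_condition <- function() {
  expression_condition(w_mult = exp(stats::runif(1, -2, 2)),
                       a_mult = exp(stats::runif(1, -2, 2)))
}

# Independent oracle: species probabilities from the textbook formulas with
# naive exponentials (no log-space shift, no weight caching).
naive_ensemble <- function(params, cond, c, mu) {
  sp <- enumerate_species(params$x_max, params$scheme)
  pot <- linker_potentials(cond, params)
  f_on <- params$delta_eps - log(1 + c / params$kd_on) + mu
  f_off <- -log(1 + c / params$kd_off) + mu
  J <- params$j_coupling
  sym <- params$scheme %in% c("symmetric", "symmetric_wonly")
  e_a <- if (sym) 2 * pot$mu_a2 + 2 * pot$mu_w else pot$mu_a2 + 2 * pot$mu_w
  e_w <- if (sym) 4 * pot$mu_w else pot$mu_w2 + 2 * pot$mu_w
  rest <- ifelse(sp$rest == "R1", 0,
          ifelse(sp$rest == "R2", (sp$x + 2) * pot$mu_w,
                 (sp$x + 2) * (pot$mu_w + (if (sym) 2 else 1) * pot$mu_a2)))
  term <- function(n, e) ifelse(n > 0, n * e, 0)  # 0 slots contribute 0
  F_on <- 3 * sp$x * f_on + term(sp$n_linkers_a, e_a + J) +
    term(sp$n_linkers_w, e_w + J) + rest
  F_off <- 3 * sp$x * f_off + term(sp$n_linkers_a, e_a) +
    term(sp$n_linkers_w, e_w) + rest
  w <- sp$multiplicity * (exp(-F_on) + exp(-F_off))
  Z <- 1 + sum(w)
  list(species = sp, p_species = w / Z, p_empty = 1 / Z,
       p_on = 1 / (1 + exp(F_on - F_off)),
       rho = sum(3 * sp$x * w / Z),
       activity = sum(w / Z * (1 / (1 + exp(F_on - F_off))) * sp$n_a2))
}
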