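#' Single-dimer free energies of the two receptor conformations
#'
#' For a receptor dimer with modification offset `delta_eps` and
#' conformation-dependent dissociation constants, the free energies (kT)
#' at ligand concentration `c` are
#' `f_on = delta_eps - log(1 + c/kd_on) + mu` and
#' `f_off = -log(1 + c/kd_off) + mu`, with `mu` the membrane chemical
#' potential per dimer. Because the inactive state binds ligand more
#' tightly (`kd_off < kd_on`), increasing `c` lowers `f_off` faster than
#' `f_on` and tips complexes towards the inactive state.
#'
#' @param c Ligand concentration(s), mM; nonnegative. Vectorized.
#' @param delta_eps Active-state energy offset (kT).
#' @param kd_on,kd_off Dissociation constants (mM) of the active/inactive
#'   conformations.
#' @param mu Chemical potential per dimer (kT).
#' @return List with numeric vectors `f_on` and `f_off`.
#' @examples
#' dimer_free_energies(0, delta_eps = -2.42, kd_on = 2.18, kd_off = 0.002)
#' @export
dimer_free_energies <- function(c, delta_eps, kd_on, kd_off, mu = 0) {
  if (any(c < 0)) stop("ligand concentration must be nonnegative", call. = FALSE)
  if (!(kd_on > 0 && kd_off > 0)) stop("dissociation constants must be positive",
                                       call. = FALSE)
  list(f_on = delta_eps - log1p(c / kd_on) + mu,
       f_off = -log1p(c / kd_off) + mu)
}

#' Linker-protein chemical potentials at a given expression condition
#'
#' The chemical potential of a protein integrated into a complex scales
#' with the log of its free concentration: at `i` times the wild-type CheW
#' level, `mu_w = mu_w0 - log(i)`, and at `j` times the wild-type CheA
#' level, `mu_a2 = mu_a2_0 - log(j)` (more protein makes incorporation
#' cheaper). The CheW2 core of a CheW-only linker contains two CheW
#' monomers, so its potential scales twice as fast: `mu_w2 = mu_w2_0 -
#' 2 log(i)`. The no-CheA limit `a_mult = 0` returns `mu_a2 = Inf`, which
#' gives every CheA-containing species zero statistical weight.
#'
#' @param cond An [expression_condition()].
#' @param params An [ensemble_parameters()] object.
#' @return List with `mu_w`, `mu_a2` and (for the `bridged_wonly` scheme)
#'   `mu_w2`, all in kT.
#' @examples
#' p <- caption_parameters("expression_series")
#' linker_potentials(expression_condition(10, 1), p)
#' @export
linker_potentials <- function(cond, params) {
  stopifnot(inherits(cond, "expression_condition"),
            inherits(params, "ensemble_params"))
  mu_w <- params$mu_w0 - log(cond$w_mult)
  mu_a2 <- if (cond$a_mult > 0) params$mu_a2_0 - log(cond$a_mult) else Inf
  mu_w2 <- if (params$scheme == "bridged_wonly") {
    params$mu_w2_0 - 2 * log(cond$w_mult)
  } else NA_real_
  list(mu_w = mu_w, mu_a2 = mu_a2, mu_w2 = mu_w2)
}

# n * e with the convention 0 * Inf = 0 (absent linker types contribute
# nothing even when their potential is the +Inf sentinel)
.nx <- function(n, e) ifelse(n > 0, n * e, 0)

# species tables and the numeric columns used in the hot path, memoized per
# (x_max, scheme): the density solver re-evaluates the ensemble thousands of
# times per dose-response sweep
.species_cache <- new.env(parent = emptyenv())

species_cached <- function(x_max, scheme) {
  key <- paste0(scheme, ":", x_max)
  hit <- .species_cache[[key]]
  if (!is.null(hit)) return(hit)
  sp <- enumerate_species(x_max, scheme)
  val <- list(
    table = sp,
    x = sp$x, x3 = 3 * sp$x,
    n_la = sp$n_linkers_a, n_lw = sp$n_linkers_w,
    n_link = sp$n_linkers_a + sp$n_linkers_w,
    n_a2 = sp$n_a2,
    log_mult = log(sp$multiplicity),
    rest_sites = sp$x + 2L,
    is_r2 = sp$rest == "R2", is_r3 = sp$rest == "R3"
  )
  assign(key, val, envir = .species_cache)
  val
}

# Per-species free-energy pieces that do not depend on mu, evaluated at
# mu = 0. mu enters each species' energy only as 3x * mu, so weights at any
# mu are the mu = 0 weights times exp(-3x * mu); solve_mu exploits this.
# Returns log Boltzmann weights (including multiplicity) and the finite
# on/off energy gap.
ensemble_logweights <- function(params, cond, c, species = NULL) {
  sp <- if (is.null(species)) species_cached(params$x_max, params$scheme)
        else species
  pot <- linker_potentials(cond, params)
  f <- dimer_free_energies(c, params$delta_eps, params$kd_on, params$kd_off,
                           mu = 0)
  J <- params$j_coupling
  sym <- scheme_is_symmetric(params$scheme)

  # per-linker off-state energies; the coupling J is added per linker of
  # either type in the on state only
  e_link_a <- if (sym) 2 * pot$mu_a2 + 2 * pot$mu_w else pot$mu_a2 + 2 * pot$mu_w
  e_link_w <- if (sym) 4 * pot$mu_w else pot$mu_w2 + 2 * pot$mu_w
  e_r2 <- pot$mu_w
  e_r3 <- pot$mu_w + (if (sym) 2 else 1) * pot$mu_a2

  rest_e <- sp$rest_sites * (e_r2 * sp$is_r2 + 0) # R1 contributes 0
  rest_e[sp$is_r3] <- sp$rest_sites[sp$is_r3] * e_r3
  link_off <- .nx(sp$n_la, e_link_a) + .nx(sp$n_lw, e_link_w)

  f_off_tot <- sp$x3 * f$f_off + link_off + rest_e
  dF <- sp$x3 * (f$f_on - f$f_off) + sp$n_link * J  # always finite
  f_on_tot <- f_off_tot + dF

  list(species = sp,
       lw_on = sp$log_mult - f_on_tot,
       lw_off = sp$log_mult - f_off_tot,
       dF = dF)
}

# Assemble the normalized ensemble from cached mu = 0 log-weights.
# Evaluated in log space relative to the maximum weight so that arbitrarily
# large |mu| (needed while bracketing the density constraint) cannot
# overflow.
ensemble_from_logweights <- function(lw, mu, c) {
  sp <- lw$species
  a <- lw$lw_on - sp$x3 * mu
  b <- lw$lw_off - sp$x3 * mu
  m <- max(a, b, 0)
  wa <- exp(a - m); wb <- exp(b - m)
  z <- exp(-m) + sum(wa) + sum(wb)      # Z / e^m
  p_species <- (wa + wb) / z
  p_empty <- exp(-m) / z
  p_on <- 1 / (1 + exp(lw$dF))          # conditional on the species
  structure(
    list(
      c = c, mu = mu,
      species = sp$table,
      p_species = p_species, p_on = p_on, p_empty = p_empty,
      activity = sum(p_species * p_on * sp$n_a2),
      rho = sum(sp$x3 * p_species)
    ),
    class = "ensemble_state"
  )
}

# density only, for the root search: no state object allocation
rho_at_mu <- function(lw, mu) {
  sp <- lw$species
  a <- lw$lw_on - sp$x3 * mu
  b <- lw$lw_off - sp$x3 * mu
  m <- max(a, b, 0)
  wa <- exp(a - m); wb <- exp(b - m)
  sum(sp$x3 * (wa + wb)) / (exp(-m) + sum(wa) + sum(wb))
}

#' Equilibrium ensemble of receptor complexes at fixed chemical potential
#'
#' Evaluates the grand-canonical ensemble over all complex species (plus
#' the empty membrane site) at one ligand concentration and one chemical
#' potential. Each species' active/inactive Boltzmann weights follow from
#' the complex free energies: `3x` single-dimer energies, one linker energy
#' per filled linker slot (plus the coupling `J` per linker in the active
#' state), and the symmetric rest-group energy. The kinase activity is the
#' expectation of CheA2 dimers in active complexes,
#' `A = sum(P_S * P_S_on * n_a2)`, and the receptor density is
#' `rho = sum(3x * P_S)`.
#'
#' Weights are computed in log space relative to the dominant weight, so
#' extreme chemical potentials do not overflow.
#'
#' @param params An [ensemble_parameters()] object.
#' @param cond An [expression_condition()].
#' @param c Ligand concentration (mM, scalar).
#' @param mu Chemical potential per receptor dimer (kT).
#' @return An object of class `ensemble_state` with elements `c`, `mu`,
#'   `species` (the [enumerate_species()] table), `p_species`, `p_on`
#'   (conditional activity probability per species), `p_empty`, `activity`
#'   and `rho`. Probabilities sum to one: `sum(p_species) + p_empty == 1`.
#' @examples
#' p <- caption_parameters("expression_series")
#' s <- ensemble_state(p, expression_condition(), c = 0.01, mu = 0)
#' s$rho
#' @export
ensemble_state <- function(params, cond = expression_condition(), c, mu) {
  stopifnot(inherits(params, "ensemble_params"), length(c) == 1L,
            length(mu) == 1L, is.finite(mu))
  if (c < 0) stop("ligand concentration must be nonnegative", call. = FALSE)
  lw <- ensemble_logweights(params, cond, c)
  ensemble_from_logweights(lw, mu, c)
}

#' @export
print.ensemble_state <- function(x, ...) {
  cat(sprintf(
    "<ensemble_state> c = %g mM, mu = %.4g kT\n  rho = %.4g dimers/site, activity = %.4g, P(empty) = %.4g\n",
    x$c, x$mu, x$rho, x$activity, x$p_empty))
  invisible(x)
}
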