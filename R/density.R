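#' Solve for the chemical potential that enforces the target density
#'
#' The receptor density `rho(mu) = sum(3x * P_S)` is strictly decreasing
#' in the chemical potential `mu` (raising the per-dimer cost depopulates
#' every species in favour of the empty site), so the density constraint
#' `rho(mu) = rho_target` has a unique root. It is located with Brent's
#' method ([stats::uniroot()]) inside a bracket grown by doubling outward
#' from `[-50, 50]` kT up to `|mu| = 500` kT.
#'
#' Because `mu` enters every species weight only through the factor
#' `exp(-3x * mu)`, the concentration-dependent part of the weights is
#' computed once per call and only the cheap `mu` shift is re-evaluated
#' inside the root search.
#'
#' @param params An [ensemble_parameters()] object.
#' @param cond An [expression_condition()].
#' @param c Ligand concentration (mM, scalar).
#' @param rho_target Target mean dimer count per site; defaults to
#'   `params$rho`. Must lie in `(0, 3 * x_max)`.
#' @param tol Absolute tolerance on the achieved density (default 1e-10).
#' @param mu_init Optional initial guess (kT); a warm start from a
#'   neighbouring concentration tightens the initial bracket.
#' @return An object of class `mu_solution`: list with `mu`,
#'   `rho_achieved`, `iterations`, `converged` and the `ensemble_state`
#'   evaluated at the solution (element `state`).
#' @examples
#' p <- caption_parameters("expression_series")
#' solve_mu(p, expression_condition(), c = 0.01)
#' @export
solve_mu <- function(params, cond = expression_condition(), c,
                     rho_target = params$rho, tol = 1e-10, mu_init = NULL) {
  stopifnot(inherits(params, "ensemble_params"))
  if (!(rho_target > 0 && rho_target < 3 * params$x_max))
    stop(sprintf("rho_target must lie in (0, %d)", 3L * params$x_max),
         call. = FALSE)

  lw <- ensemble_logweights(params, cond, c)
  rho_of <- function(mu) rho_at_mu(lw, mu)
  f <- function(mu) rho_at_mu(lw, mu) - rho_target

  # rho(mu) is decreasing: need f(lo) > 0 > f(hi)
  lo <- if (is.null(mu_init)) -50 else mu_init - 1
  hi <- if (is.null(mu_init)) 50 else mu_init + 1
  expansions <- 0L
  while (f(lo) < 0 && lo > -500) { lo <- max(-500, 2 * lo - hi); expansions <- expansions + 1L }
  while (f(hi) > 0 && hi < 500) { hi <- min(500, 2 * hi - lo); expansions <- expansions + 1L }
  if (f(lo) < 0 || f(hi) > 0)
    stop(sprintf(
      "density constraint not bracketable: rho(%g) = %.6g, rho(%g) = %.6g, target %.6g",
      lo, rho_of(lo), hi, rho_of(hi), rho_target), call. = FALSE)

  root <- stats::uniroot(f, lower = lo, upper = hi, tol = 1e-13,
                         maxiter = 1000L)
  state <- ensemble_from_logweights(lw, root$root, c)
  structure(
    list(mu = root$root, rho_achieved = state$rho,
         iterations = root$iter + expansions,
         converged = abs(state$rho - rho_target) <= tol,
         state = state),
    class = "mu_solution"
  )
}

#' @export
print.mu_solution <- function(x, ...) {
  cat(sprintf("<mu_solution> mu = %.6g kT, rho = %.8g (%s, %d iterations)\n",
              x$mu, x$rho_achieved,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Ensemble at fixed chemical potential (density left free)
#'
#' Companion mode to the density-constrained solver: the chemical
#' potential is held fixed and the receptor density floats with ligand
#' concentration. Because single-dimer energies fall with `c` and larger
#' complexes gain `3x` such terms, density grows with concentration and
#' approaches the maximum `3 * x_max` at saturating ligand; for suitable
#' fixed `mu` this produces a non-monotone "bump" in the dose-response
#' curve instead of a clean sigmoid.
#'
#' @inheritParams ensemble_state
#' @return An `ensemble_state` (see [ensemble_state()]).
#' @examples
#' p <- caption_parameters("tar_modification", mod = "QEQE")
#' constant_mu_state(p, c = 1e6, mu = 3.8)$rho  # near the maximum of 12
#' @export
constant_mu_state <- function(params, cond = expression_condition(), c, mu) {
  ensemble_state(params, cond, c, mu)
}
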