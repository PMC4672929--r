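#' Logarithmically spaced concentration grid
#'
#' The standard grid used for all Hill-coefficient reproductions is 50
#' log-spaced concentrations between 0.001 mM and 1 mM.
#'
#' @param n Number of points.
#' @param cmin,cmax Grid endpoints (mM).
#' @return Numeric vector of concentrations, strictly increasing.
#' @export
concentration_grid <- function(n = 50L, cmin = 1e-3, cmax = 1) {
  if (!(cmin > 0 && cmax > cmin)) stop("need 0 < cmin < cmax", call. = FALSE)
  exp(seq(log(cmin), log(cmax), length.out = n))
}

#' Dose-response curve of the receptor ensemble
#'
#' Evaluates the kinase activity across a ligand-concentration grid. In
#' `"constant_rho"` mode (the model's native mode) the chemical potential
#' is re-solved at each concentration so the receptor density stays at
#' `params$rho`; the solved `mu` at one concentration warm-starts the
#' bracket at the next. In `"constant_mu"` mode the supplied `mu` is held
#' fixed and the density floats.
#'
#' @param params An [ensemble_parameters()] object.
#' @param cond An [expression_condition()].
#' @param grid Strictly increasing concentrations (mM); defaults to the
#'   standard 50-point log grid on `[0.001, 1]` mM.
#' @param mode `"constant_rho"` or `"constant_mu"`.
#' @param mu Fixed chemical potential (kT), required for `"constant_mu"`.
#' @return An object of class `dose_response`: a data frame with columns
#'   `c_mM`, `activity`, `mu`, `rho`, carrying the mode and condition as
#'   attributes.
#' @examples
#' p <- caption_parameters("expression_series")
#' dr <- dose_response(p, expression_condition(0.7, 1))
#' head(dr)
#' @export
dose_response <- function(params, cond = expression_condition(),
                          grid = concentration_grid(),
                          mode = c("constant_rho", "constant_mu"),
                          mu = NULL) {
  mode <- match.arg(mode)
  if (length(grid) < 1L || any(diff(grid) <= 0) || any(grid <= 0))
    stop("grid must be strictly increasing and positive", call. = FALSE)
  n <- length(grid)
  act <- mu_out <- rho_out <- numeric(n)
  mu_prev <- NULL
  for (k in seq_len(n)) {
    if (mode == "constant_rho") {
      sol <- tryCatch(
        solve_mu(params, cond, grid[k], mu_init = mu_prev),
        error = function(e) stop(sprintf("density solve failed at c = %g mM: %s",
                                         grid[k], conditionMessage(e)),
                                 call. = FALSE))
      st <- sol$state
      mu_prev <- sol$mu
    } else {
      if (is.null(mu)) stop("mode 'constant_mu' requires mu", call. = FALSE)
      st <- ensemble_state(params, cond, grid[k], mu)
    }
    act[k] <- st$activity; mu_out[k] <- st$mu; rho_out[k] <- st$rho
  }
  structure(
    data.frame(c_mM = grid, activity = act, mu = mu_out, rho = rho_out),
    mode = mode, condition = cond, class = c("dose_response", "data.frame")
  )
}

#' Fit a Hill function to a dose-response curve
#'
#' Fits the decreasing Hill sigmoid `A(c) = A0 / (1 + (c / c_half)^n_hill)`
#' by Levenberg-Marquardt nonlinear least squares
#' ([minpack.lm::nlsLM()]). Starting values: `A0` at the maximum activity,
#' `c_half` at the grid point nearest half-maximum, `n_hill = 2`; all three
#' parameters are bounded below by zero. The Hill coefficient `n_hill`
#' quantifies the cooperativity of the response and is distinct from the
#' number of coupled receptors.
#'
#' @param curve A [dose_response()] object, or a numeric vector of
#'   concentrations (mM) when `activities` is supplied separately.
#' @param activities Activities matching `curve` when it is a bare
#'   concentration vector.
#' @return An object of class `hill_fit`: list with `amplitude`, `c_half`
#'   (mM), `n_hill`, `rss` and `converged`.
#' @examples
#' cc <- concentration_grid()
#' a <- 0.5 / (1 + (cc / 0.1)^2)
#' hill_fit(cc, a)
#' @export
hill_fit <- function(curve, activities = NULL) {
  if (inherits(curve, "dose_response")) {
    cc <- curve$c_mM; a <- curve$activity
  } else {
    cc <- as.numeric(curve); a <- as.numeric(activities)
  }
  if (length(cc) < 4L) stop("need at least 4 points for a Hill fit",
                            call. = FALSE)
  if (length(cc) != length(a)) stop("length mismatch", call. = FALSE)
  if (all(a == 0)) stop("cannot fit a Hill function to an all-zero curve",
                        call. = FALSE)

  a0 <- max(a)
  ch <- cc[which.min(abs(a - a0 / 2))]
  dat <- data.frame(cc = cc, a = a)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      a ~ A0 / (1 + (cc / cH)^nH), data = dat,
      start = list(A0 = a0, cH = ch, nH = 2),
      lower = c(A0 = 0, cH = 1e-12, nH = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(list(amplitude = NA_real_, c_half = NA_real_,
                          n_hill = NA_real_, rss = NA_real_,
                          converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "hill_fit"))
  }
  cf <- stats::coef(fit)
  structure(
    list(amplitude = unname(cf["A0"]), c_half = unname(cf["cH"]),
         n_hill = unname(cf["nH"]),
         rss = sum(stats::resid(fit)^2), converged = TRUE),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<hill_fit> NOT converged:", x$message, "\n")
  } else {
    cat(sprintf("<hill_fit> A0 = %.4g, c_half = %.4g mM, n_H = %.3g (rss = %.3g)\n",
                x$amplitude, x$c_half, x$n_hill, x$rss))
  }
  invisible(x)
}

#' Activity of the classical MWC model of a single receptor complex
#'
#' The classical all-or-none description of one complex of `n` trimers of
#' dimers (no explicit linker proteins):
#' `A = 1 / (1 + exp(n * (delta_eps + log((1 + c/kd_off) / (1 + c/kd_on)))))`.
#' Its fitted Hill coefficient approaches `n` only when `c` is far below
#' `kd_on`; the two are not interchangeable measures of cooperativity.
#'
#' @param c Ligand concentration(s), mM. Vectorized.
#' @param n Complex size (number of units sharing one conformational
#'   state); `n >= 1`.
#' @param delta_eps Active-state offset per unit (kT).
#' @param kd_on,kd_off Active/inactive dissociation constants (mM).
#' @return Activity in `[0, 1]`, same length as `c`.
#' @examples
#' classical_mwc_activity(0.1, n = 6, delta_eps = -1, kd_on = 0.5, kd_off = 0.02)
#' @export
classical_mwc_activity <- function(c, n, delta_eps, kd_on, kd_off) {
  if (n < 1) stop("complex size n must be >= 1", call. = FALSE)
  if (any(c < 0)) stop("ligand concentration must be nonnegative", call. = FALSE)
  arg <- n * (delta_eps + log1p(c / kd_off) - log1p(c / kd_on))
  1 / (1 + exp(arg))
}

#' Hill-parameter scan over CheW and CheA expression levels
#'
#' Computes a density-constrained dose-response and its Hill fit at every
#' combination of the supplied expression multipliers, e.g. to map the
#' amplitude and cooperativity surfaces over several orders of magnitude
#' of CheW/CheA expression. Conditions whose Hill fit fails are kept with
#' `NA` fit columns.
#'
#' @param params An [ensemble_parameters()] object.
#' @param w_grid,a_grid Positive expression multipliers for CheW and CheA.
#' @param grid Concentration grid (mM).
#' @return Data frame with columns `w_mult`, `a_mult`, `amplitude`,
#'   `c_half`, `n_hill`.
#' @export
scan_expression <- function(params, w_grid = 1, a_grid = 1,
                            grid = concentration_grid()) {
  if (any(w_grid <= 0) || any(a_grid <= 0))
    stop("expression grids must be positive", call. = FALSE)
  combos <- expand.grid(w_mult = w_grid, a_mult = a_grid,
                        KEEP.OUT.ATTRS = FALSE)
  fits <- lapply(seq_len(nrow(combos)), function(k) {
    cond <- expression_condition(combos$w_mult[k], combos$a_mult[k])
    h <- tryCatch(hill_fit(dose_response(params, cond, grid)),
                  error = function(e) NULL)
    if (is.null(h) || !h$converged) {
      c(amplitude = NA_real_, c_half = NA_real_, n_hill = NA_real_)
    } else {
      c(amplitude = h$amplitude, c_half = h$c_half, n_hill = h$n_hill)
    }
  })
  cbind(combos, do.call(rbind, fits))
}

#' Expected fraction of linkers that contain CheA
#'
#' Over the species distribution of an [ensemble_state()], the expected
#' number of CheW/CheA2 linkers divided by the expected number of linkers
#' of either type. Under the base bridged scheme every linker contains
#' CheA, so the ratio is identically 1; with CheW-only linkers enabled the
#' ratio falls below 1 as CheW-only linkers displace CheA from the lattice.
#'
#' @param state An `ensemble_state`.
#' @return A single number in `[0, 1]`.
#' @export
chea_per_linker <- function(state) {
  stopifnot(inherits(state, "ensemble_state"))
  sp <- state$species
  e_a <- sum(state$p_species * sp$n_linkers_a)
  e_all <- sum(state$p_species * (sp$n_linkers_a + sp$n_linkers_w))
  if (e_all <= .Machine$double.eps)
    stop("expected linker count is zero; CheA-per-linker ratio undefined",
         call. = FALSE)
  e_a / e_all
}
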