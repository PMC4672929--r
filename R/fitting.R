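#' Squared-deviation objective against a dose-response dataset
#'
#' For every condition in the dataset the density-constrained model
#' activity is evaluated at the recorded concentrations, multiplied by the
#' condition family's signal scale, and compared with the recorded
#' signals: `chi2 = sum((s_family * A_model(c) - signal)^2)`. FRET
#' amplitudes are only known up to a proportionality constant, so one
#' multiplicative scale per condition family (e.g. one for a CheW series
#' and one for a CheA series) converts model activities to signal units.
#'
#' When `scales` is `NULL` each family's scale is profiled out
#' analytically: the least-squares optimum for fixed model activities is
#' `s = sum(A * y) / sum(A^2)`.
#'
#' @param params An [ensemble_parameters()] object.
#' @param data A [fret_dataset()] (or data frame with its columns).
#' @param scales Named numeric vector of per-family scales, or `NULL` to
#'   profile them analytically.
#' @return The chi-square value, with the scales used attached as
#'   attribute `"scales"`.
#' @export
chi_square <- function(params, data, scales = NULL) {
  data <- as_fret_dataset(data)
  pred <- model_signal_activities(params, data)
  fam <- dataset_families(data)
  use_scales <- if (is.null(scales)) profile_scales(pred, data$signal, fam)
                else scales
  missing_fam <- setdiff(unique(fam), names(use_scales))
  if (length(missing_fam))
    stop("no scale supplied for family: ", paste(missing_fam, collapse = ", "),
         call. = FALSE)
  resid <- use_scales[fam] * pred - data$signal
  structure(sum(resid^2), scales = use_scales)
}

# model activity at each record's concentration, grouped by condition so
# the density constraint is solved once per unique (condition, c)
model_signal_activities <- function(params, data) {
  pred <- numeric(nrow(data))
  for (key in unique(data$condition)) {
    rows <- which(data$condition == key)
    cond <- expression_condition(data$w_mult[rows[1]], data$a_mult[rows[1]])
    cc <- sort(unique(data$c_mM[rows]))
    dr <- dose_response(params, cond, grid = cc)
    pred[rows] <- dr$activity[match(data$c_mM[rows], dr$c_mM)]
  }
  pred
}

dataset_families <- function(data) {
  if (!is.null(data$family)) as.character(data$family)
  else rep("all", nrow(data))
}

# closed-form least-squares scale per family
profile_scales <- function(pred, signal, fam) {
  vapply(split(seq_along(pred), fam), function(idx) {
    denom <- sum(pred[idx]^2)
    if (denom == 0) 0 else sum(pred[idx] * signal[idx]) / denom
  }, numeric(1))
}

#' Multi-start global parameter estimation
#'
#' Estimates selected model parameters from a dose-response dataset by
#' minimizing the squared deviation of scaled model activities from the
#' recorded signals. Start points fill the bounded search box with a
#' seeded Latin hypercube ([lhs::randomLHS()]); each start is refined with
#' bounded quasi-Newton local optimization (`L-BFGS-B`), and the per-family
#' signal scales are profiled analytically at every objective evaluation
#' (see [chi_square()]). Given the same seed, data and bounds the result
#' is fully reproducible.
#'
#' @param data A [fret_dataset()].
#' @param params Template [ensemble_parameters()] supplying every
#'   parameter that is not being fitted.
#' @param bounds Named list of `c(lower, upper)` ranges for the parameters
#'   to fit; names must be numeric scalar fields of the parameter object
#'   (e.g. `delta_eps`, `j_coupling`, `rho`, `mu_w0`, `mu_a2_0`, `kd_on`,
#'   `kd_off`).
#' @param n_starts Number of multi-start points (default 50).
#' @param seed Integer seed controlling start placement.
#' @return An object of class `fit_result`: list with `params` (best-fit
#'   [ensemble_parameters()]), `scales`, `chi2`, `n_starts`, `seed` and
#'   `starts` (per-start table of start point, refined point, chi2 and
#'   optimizer convergence code).
#' @examples
#' \donttest{
#' p <- caption_parameters("expression_series")
#' dat <- generate_dataset(p, list(expression_condition(0.7, 1)),
#'                         grid = concentration_grid(12), seed = 1)
#' fit_global(dat, p, bounds = list(delta_eps = c(-4, -1)),
#'            n_starts = 4, seed = 1)
#' }
#' @export
fit_global <- function(data, params, bounds, n_starts = 50L, seed = 1L) {
  data <- as_fret_dataset(data)
  stopifnot(inherits(params, "ensemble_params"), n_starts >= 1L)
  if (!length(bounds) || is.null(names(bounds)))
    stop("bounds must be a named list of c(lower, upper)", call. = FALSE)
  bad <- names(bounds)[!vapply(bounds, function(b)
    length(b) == 2L && all(is.finite(b)) && b[1] < b[2], logical(1))]
  if (length(bad))
    stop("invalid bounds for: ", paste(bad, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(bounds), names(params))
  if (length(unknown))
    stop("unknown parameter(s) in bounds: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  free <- names(bounds)
  lower <- vapply(bounds, `[`, numeric(1), 1L)
  upper <- vapply(bounds, `[`, numeric(1), 2L)

  with_theta <- function(theta) {
    p <- params
    p[free] <- as.list(theta)
    tryCatch(validate_parameters(p), error = function(e) NULL)
  }
  objective <- function(theta) {
    p <- with_theta(theta)
    if (is.null(p)) return(1e10)
    tryCatch(as.numeric(chi_square(p, data)), error = function(e) 1e10)
  }

  set.seed(seed)
  u <- lhs::randomLHS(n_starts, length(free))
  starts <- sweep(sweep(u, 2L, upper - lower, `*`), 2L, lower, `+`)
  colnames(starts) <- free

  runs <- lapply(seq_len(n_starts), function(k) {
    res <- tryCatch(
      stats::optim(starts[k, ], objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 300L)),
      error = function(e) NULL
    )
    if (is.null(res)) {
      list(par = starts[k, ], value = Inf, convergence = -1L)
    } else res
  })
  chi2s <- vapply(runs, `[[`, numeric(1), "value")
  if (all(!is.finite(chi2s)))
    stop("all optimization starts failed", call. = FALSE)

  best <- runs[[which.min(chi2s)]]
  best_params <- with_theta(best$par)
  best_chi2 <- chi_square(best_params, data)

  start_tab <- data.frame(starts, check.names = FALSE)
  names(start_tab) <- paste0("start_", free)
  fitted_tab <- do.call(rbind, lapply(runs, function(r) r$par))
  colnames(fitted_tab) <- paste0("fit_", free)
  starts_df <- cbind(start_tab, as.data.frame(fitted_tab),
                     chi2 = chi2s,
                     convergence = vapply(runs, function(r)
                       as.integer(r$convergence %||% NA_integer_), integer(1)))

  structure(
    list(params = best_params, scales = attr(best_chi2, "scales"),
         chi2 = as.numeric(best_chi2), n_starts = as.integer(n_starts),
         seed = as.integer(seed), free = free, bounds = bounds,
         starts = starts_df),
    class = "fit_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> chi2 = %.6g over %d starts (seed %d)\n",
              x$chi2, x$n_starts, x$seed))
  for (nm in x$free)
    cat(sprintf("  %-10s = %.6g  [%g, %g]\n", nm, x$params[[nm]],
                x$bounds[[nm]][1], x$bounds[[nm]][2]))
  cat("  scales:", paste(sprintf("%s = %.6g", names(x$scales), x$scales),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' @param fit A `fit_result` from [fit_global()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  out <- list(
    parameters = fit$params[setdiff(names(fit$params), "mod_label")],
    mod_label = fit$params$mod_label,
    scales = as.list(fit$scales),
    chi2 = fit$chi2, n_starts = fit$n_starts, seed = fit$seed,
    free = fit$free, bounds = fit$bounds,
    starts = fit$starts
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}
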