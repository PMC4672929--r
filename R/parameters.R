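#' Thermodynamic parameters of one receptor-ensemble model variant
#'
#' Bundles every parameter needed to evaluate the equilibrium ensemble of
#' receptor complexes: the modification-dependent free-energy offset of an
#' active receptor dimer, the conformation-dependent ligand dissociation
#' constants, the per-linker coupling energy, the wild-type chemical
#' potentials of the linker proteins, and the target receptor density
#' enforced by the membrane chemical potential.
#'
#' All energies are in units of the thermal energy kT; all concentrations
#' are in mM. The active-state dissociation constant must exceed the
#' inactive-state one (`kd_on > kd_off`): inactive receptors bind attractant
#' more tightly, so increasing ligand concentration shifts complexes towards
#' the inactive conformation.
#'
#' @param delta_eps Free-energy offset (kT) of the active state of one
#'   receptor dimer at zero ligand, set by the methylation-mimicking
#'   modification state (e.g. QEQE). Negative values favour activity.
#' @param kd_on,kd_off Ligand dissociation constants (mM) of the active and
#'   inactive receptor conformations; `kd_on > kd_off > 0`.
#' @param j_coupling Coupling energy J (kT) contributed by every linker
#'   joining two active trimers of dimers; J < 0 favours active clustering.
#' @param mu_w0 Chemical potential (kT) of one CheW monomer at wild-type
#'   CheW expression.
#' @param mu_a2_0 Chemical potential (kT) of one CheA2 dimer at wild-type
#'   CheA expression (for the symmetric schemes, of one CheA monomer).
#' @param mu_w2_0 Chemical potential (kT) of the central CheW2 unit of a
#'   CheW-only linker at wild-type expression; required by (and only used
#'   with) the `*_wonly` schemes.
#' @param rho Target receptor density: mean number of receptor dimers per
#'   membrane site, `0 < rho < 3 * x_max`.
#' @param x_max Maximal number of trimers of dimers per complex (default 4,
#'   so complexes hold up to 12 dimers).
#' @param scheme Linker architecture, one of `"bridged"` (CheA2 bridges two
#'   receptor-bound CheWs), `"bridged_wonly"` (additionally allows
#'   CheW-only linkers), `"symmetric"` (CheA and CheW both contact the
#'   trimers directly), `"symmetric_wonly"`.
#' @param mod_label Optional label of the modification state (e.g. "QEQE").
#'
#' @return An object of class `ensemble_params` (a validated list).
#' @seealso [expression_condition()], [ensemble_state()], [solve_mu()],
#'   [read_parameters()]
#' @examples
#' p <- ensemble_parameters(
#'   delta_eps = -2.42, kd_on = 2.18, kd_off = 0.002, j_coupling = -3.81,
#'   mu_w0 = -0.67, mu_a2_0 = -1.68, rho = 3.13
#' )
#' p
#' @export
ensemble_parameters <- function(delta_eps, kd_on, kd_off, j_coupling,
                                mu_w0, mu_a2_0, mu_w2_0 = NA_real_,
                                rho, x_max = 4L, scheme = "bridged",
                                mod_label = NULL) {
  scheme <- match.arg(scheme, linker_schemes())
  p <- structure(
    list(
      delta_eps = as.numeric(delta_eps),
      kd_on = as.numeric(kd_on), kd_off = as.numeric(kd_off),
      j_coupling = as.numeric(j_coupling),
      mu_w0 = as.numeric(mu_w0), mu_a2_0 = as.numeric(mu_a2_0),
      mu_w2_0 = as.numeric(mu_w2_0),
      rho = as.numeric(rho), x_max = as.integer(x_max),
      scheme = scheme, mod_label = mod_label
    ),
    class = "ensemble_params"
  )
  validate_parameters(p)
}

#' @export
print.ensemble_params <- function(x, ...) {
  cat("<ensemble_params>", if (!is.null(x$mod_label)) x$mod_label else "",
      "scheme:", x$scheme, "\n")
  cat(sprintf("  delta_eps = %.4g kT, kd_on = %.4g mM, kd_off = %.4g mM\n",
              x$delta_eps, x$kd_on, x$kd_off))
  cat(sprintf("  J = %.4g kT, mu_w0 = %.4g, mu_a2_0 = %.4g%s\n",
              x$j_coupling, x$mu_w0, x$mu_a2_0,
              if (scheme_has_wonly(x$scheme))
                sprintf(", mu_w2_0 = %.4g", x$mu_w2_0) else ""))
  cat(sprintf("  rho = %.4g dimers/site, x_max = %d\n", x$rho, x$x_max))
  invisible(x)
}

validate_parameters <- function(p) {
  stopifnot(is.finite(p$delta_eps), is.finite(p$j_coupling),
            is.finite(p$mu_w0), is.finite(p$mu_a2_0))
  if (!(p$kd_on > 0 && p$kd_off > 0))
    stop("dissociation constants must be positive", call. = FALSE)
  if (p$kd_on <= p$kd_off)
    stop("kd_on must exceed kd_off (inactive receptors bind ligand tighter)",
         call. = FALSE)
  if (p$x_max < 1L) stop("x_max must be >= 1", call. = FALSE)
  if (!(p$rho > 0 && p$rho < 3 * p$x_max))
    stop(sprintf("rho must lie in (0, %d), got %g", 3L * p$x_max, p$rho),
         call. = FALSE)
  if (scheme_has_wonly(p$scheme) && p$scheme == "bridged_wonly" &&
      !is.finite(p$mu_w2_0) && !identical(p$mu_w2_0, Inf))
    stop("scheme 'bridged_wonly' requires mu_w2_0", call. = FALSE)
  if (p$scheme == "bridged_wonly" && is.na(p$mu_w2_0))
    stop("scheme 'bridged_wonly' requires mu_w2_0", call. = FALSE)
  p
}

#' Supported linker architectures
#'
#' @return Character vector of scheme names accepted by
#'   [ensemble_parameters()].
#' @export
linker_schemes <- function() {
  c("bridged", "bridged_wonly", "symmetric", "symmetric_wonly")
}

scheme_has_wonly <- function(scheme) {
  scheme %in% c("bridged_wonly", "symmetric_wonly")
}

scheme_is_symmetric <- function(scheme) {
  scheme %in% c("symmetric", "symmetric_wonly")
}

#' Expression levels of CheW and CheA relative to wild type
#'
#' @param w_mult CheW level as a multiple i of the wild-type concentration;
#'   must be > 0.
#' @param a_mult CheA level as a multiple j of the wild-type concentration;
#'   `a_mult = 0` is allowed as the no-CheA limit, in which every
#'   CheA-containing species receives zero statistical weight.
#'
#' @return An object of class `expression_condition`.
#' @examples
#' expression_condition(0.7, 1)  # 0.7x CheW, wild-type CheA
#' @export
expression_condition <- function(w_mult = 1, a_mult = 1) {
  if (!(is.numeric(w_mult) && length(w_mult) == 1L && w_mult > 0))
    stop("w_mult must be a single positive number", call. = FALSE)
  if (!(is.numeric(a_mult) && length(a_mult) == 1L && a_mult >= 0))
    stop("a_mult must be a single nonnegative number", call. = FALSE)
  structure(list(w_mult = as.numeric(w_mult), a_mult = as.numeric(a_mult)),
            class = "expression_condition")
}

#' @export
print.expression_condition <- function(x, ...) {
  cat(sprintf("<expression_condition> [W] = %g x WT, [A] = %g x WT\n",
              x$w_mult, x$a_mult))
  invisible(x)
}

#' Read a model parameter set from a JSON or YAML config file
#'
#' The config must provide the keys `delta_eps`, `kd_on`, `kd_off`, `J`,
#' `mu_w0`, `mu_a2_0`, `rho`; optional keys are `mu_w2_0`, `x_max`
#' (default 4), `scheme` (default "bridged") and `mod_label`. The format is
#' chosen by file extension (`.json` vs `.yml`/`.yaml`).
#'
#' @param path Path to the config file.
#' @return An [ensemble_parameters()] object.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  required <- c("delta_eps", "kd_on", "kd_off", "J", "mu_w0", "mu_a2_0", "rho")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("config is missing required key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ensemble_parameters(
    delta_eps = cfg$delta_eps, kd_on = cfg$kd_on, kd_off = cfg$kd_off,
    j_coupling = cfg$J, mu_w0 = cfg$mu_w0, mu_a2_0 = cfg$mu_a2_0,
    mu_w2_0 = if (is.null(cfg$mu_w2_0)) NA_real_ else cfg$mu_w2_0,
    rho = cfg$rho,
    x_max = if (is.null(cfg$x_max)) 4L else cfg$x_max,
    scheme = if (is.null(cfg$scheme)) "bridged" else tolower(cfg$scheme),
    mod_label = cfg$mod_label
  )
}

#' Published caption parameter sets
#'
#' Convenience constructors for the parameter sets printed alongside the
#' model's reference figures: `"tar_modification"` (Tar-only cells;
#' QEQE/QEQQ/QQQQ modification series, shared density rho = 10.30),
#' `"expression_series"` (Tsr/Tar-Tsr-Tap cells, QEQE; the shared set used
#' for both the CheW and the CheA expression series, rho = 3.13) and
#' `"wonly_series"` (the CheW-only-linker variant; separate densities were
#' fitted for the CheW series, rho_W = 3.52, and the CheA series,
#' rho_A = 4.45 — select with `family`).
#'
#' @param set Which published set to return.
#' @param mod Modification state for `"tar_modification"`.
#' @param family For `"wonly_series"`: `"W"` (CheW series density) or
#'   `"A"` (CheA series density).
#' @return An [ensemble_parameters()] object.
#' @examples
#' caption_parameters("expression_series")
#' @export
caption_parameters <- function(set = c("expression_series",
                                       "tar_modification",
                                       "wonly_series"),
                               mod = c("QEQE", "QEQQ", "QQQQ"),
                               family = c("W", "A")) {
  set <- match.arg(set)
  switch(set,
    tar_modification = {
      mod <- match.arg(mod)
      de <- c(QEQE = -1.12, QEQQ = -2.16, QQQQ = -3.03)[[mod]]
      ensemble_parameters(delta_eps = de, kd_on = 2.18, kd_off = 0.001,
                          j_coupling = -3.81, mu_w0 = -0.67, mu_a2_0 = -1.68,
                          rho = 10.30, mod_label = mod)
    },
    expression_series = ensemble_parameters(
      delta_eps = -2.42, kd_on = 2.18, kd_off = 0.002, j_coupling = -3.81,
      mu_w0 = -0.67, mu_a2_0 = -1.68, rho = 3.13, mod_label = "QEQE"
    ),
    wonly_series = {
      family <- match.arg(family)
      ensemble_parameters(
        delta_eps = -1.79, kd_on = 3.53, kd_off = 0.003, j_coupling = -4.07,
        mu_w0 = -0.83, mu_a2_0 = -1.65, mu_w2_0 = -5.02,
        rho = if (family == "W") 3.52 else 4.45,
        scheme = "bridged_wonly", mod_label = "QEQE"
      )
    }
  )
}
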