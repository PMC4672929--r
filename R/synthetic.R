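#' FRET-like dose-response dataset
#'
#' A `fret_dataset` is a data frame with one row per measured point and
#' columns `condition` (label), `w_mult`, `a_mult` (expression multipliers),
#' `mod` (modification-state label), `c_mM` (ligand concentration, mM) and
#' `signal`; an optional `family` column groups conditions that share one
#' signal scale, and an optional `noise_sd` column records the generating
#' noise level.
#'
#' @param df Data frame with at least the required columns.
#' @return The validated `fret_dataset`.
#' @export
as_fret_dataset <- function(df) {
  req <- c("condition", "w_mult", "a_mult", "c_mM", "signal")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(df$c_mM <= 0))
    stop("dataset concentrations must be positive", call. = FALSE)
  counts <- table(df$condition)
  if (any(counts < 4L))
    stop("every condition needs at least 4 points; short: ",
         paste(names(counts)[counts < 4L], collapse = ", "), call. = FALSE)
  class(df) <- unique(c("fret_dataset", class(df)))
  df
}

#' Generate a synthetic FRET-like dose-response dataset
#'
#' Emulates the statistical structure of in vivo FRET dose-response
#' measurements: per-condition sigmoidal activity curves on a
#' log-spaced concentration grid, multiplied by an unknown overall signal
#' scale, with additive homoscedastic Gaussian noise. The underlying
#' activities are the model's own density-constrained dose-response
#' curves, so noiseless data round-trip through [chi_square()] to exactly
#' zero at the generating parameters.
#'
#' @param params Generating [ensemble_parameters()].
#' @param conditions List of [expression_condition()] objects (optionally
#'   named; names become condition labels).
#' @param grid Concentration grid (mM); default the standard 50-point grid.
#'   Repeated values are allowed and model replicate measurements: the
#'   model is evaluated once per unique concentration.
#' @param scale Multiplicative signal scale (> 0) applied to all
#'   conditions.
#' @param noise_sd Standard deviation of the additive Gaussian noise, in
#'   signal units; 0 gives noiseless data.
#' @param seed Integer seed; the same seed reproduces the same table.
#' @param family Optional family label(s) for the conditions (recycled);
#'   defaults to one shared family.
#' @return A [as_fret_dataset()] data frame.
#' @examples
#' p <- caption_parameters("expression_series")
#' d <- generate_dataset(p, list(wt = expression_condition(1, 1)),
#'                       grid = concentration_grid(10), seed = 42)
#' head(d)
#' @export
generate_dataset <- function(params, conditions,
                             grid = concentration_grid(),
                             scale = 1, noise_sd = 0, seed = NULL,
                             family = "all") {
  stopifnot(inherits(params, "ensemble_params"))
  if (!is.list(conditions) || !length(conditions) ||
      !all(vapply(conditions, inherits, logical(1), "expression_condition")))
    stop("conditions must be a list of expression_condition objects",
         call. = FALSE)
  if (!(is.numeric(scale) && scale > 0)) stop("scale must be > 0", call. = FALSE)
  if (!(is.numeric(noise_sd) && noise_sd >= 0))
    stop("noise_sd must be >= 0", call. = FALSE)
  # replicate measurements at one concentration are allowed: the grid only
  # needs to be positive and sorted
  if (any(grid <= 0) || any(diff(grid) < 0))
    stop("grid must be positive and non-decreasing", call. = FALSE)

  labels <- names(conditions)
  if (is.null(labels) || any(labels == "")) {
    labels <- vapply(conditions, function(cd)
      sprintf("W%g_A%g", cd$w_mult, cd$a_mult), character(1))
  }
  family <- rep_len(family, length(conditions))

  if (!is.null(seed)) set.seed(seed)
  cc_unique <- unique(grid)
  parts <- lapply(seq_along(conditions), function(k) {
    cond <- conditions[[k]]
    dr_u <- dose_response(params, cond, cc_unique)
    dr <- list(activity = dr_u$activity[match(grid, dr_u$c_mM)])
    data.frame(
      condition = labels[k],
      w_mult = cond$w_mult, a_mult = cond$a_mult,
      mod = params$mod_label %||% NA_character_,
      family = family[k],
      c_mM = grid,
      signal = scale * dr$activity +
        if (noise_sd > 0) stats::rnorm(length(grid), 0, noise_sd) else 0,
      noise_sd = noise_sd,
      stringsAsFactors = FALSE
    )
  })
  as_fret_dataset(do.call(rbind, parts))
}

#' Read/write FRET-like datasets as CSV
#'
#' The CSV dialect carries the header
#' `condition,w_mult,a_mult,mod,c_mM,signal` plus any optional columns
#' (`family`, `noise_sd`). Values round-trip at full double precision.
#'
#' @param data A [as_fret_dataset()].
#' @param path File path.
#' @return `write_fret_csv()` returns `path` invisibly; `read_fret_csv()`
#'   returns the dataset.
#' @export
write_fret_csv <- function(data, path) {
  data <- as_fret_dataset(data)
  df <- as.data.frame(data)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fret_csv
#' @export
read_fret_csv <- function(path) {
  as_fret_dataset(utils::read.csv(path, stringsAsFactors = FALSE))
}
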