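#' Enumerate the receptor-complex species of the ensemble
#'
#' A complex of size `x` contains `3x` receptor dimers (x trimers of
#' dimers), `x - 1` linker slots and `x + 2` peripheral rest-group sites.
#' Each linker slot holds either a CheW/CheA2 linker or, under the
#' `*_wonly` schemes, a CheW-only linker; mixtures are allowed and the
#' `choose(x - 1, n_linkers_a)` arrangements of a given composition are
#' collapsed into one species with that binomial multiplicity. Rest groups
#' are developed symmetrically: either absent (`R1`), a CheW on every site
#' (`R2`), or a CheW plus a CheA2 dimer on every site (`R3`). The empty
#' membrane site is not a species; it enters the partition function as the
#' constant 1.
#'
#' @param x_max Maximal number of trimers of dimers per complex.
#' @param scheme Linker architecture (see [linker_schemes()]).
#'
#' @return A data frame with one row per species and columns
#'   `x`, `rest`, `n_linkers_a`, `n_linkers_w`, `multiplicity`,
#'   `n_w` (total CheW monomers), `n_a2` (total CheA2 dimers, linkers plus
#'   rest groups), `n_dimers` (= 3x). Under `"bridged"` with `x_max = 4`
#'   the table has 12 rows; `"bridged_wonly"` has 30.
#' @examples
#' nrow(enumerate_species(4, "bridged"))        # 12
#' nrow(enumerate_species(4, "bridged_wonly"))  # 30
#' @export
enumerate_species <- function(x_max = 4L, scheme = "bridged") {
  scheme <- match.arg(scheme, linker_schemes())
  x_max <- as.integer(x_max)
  if (is.na(x_max) || x_max < 1L) stop("x_max must be >= 1", call. = FALSE)
  wonly <- scheme_has_wonly(scheme)

  rows <- vector("list", 0L)
  for (x in seq_len(x_max)) {
    n_la_options <- if (wonly) 0:(x - 1L) else x - 1L
    for (rest in c("R1", "R2", "R3")) {
      for (n_la in n_la_options) {
        n_lw <- (x - 1L) - n_la
        rest_w <- if (rest == "R1") 0L else x + 2L
        rest_a2 <- if (rest == "R3") x + 2L else 0L
        rows[[length(rows) + 1L]] <- data.frame(
          x = x, rest = rest,
          n_linkers_a = n_la, n_linkers_w = n_lw,
          multiplicity = choose(x - 1L, n_la),
          # a bridged linker carries 2 CheW monomers, a CheW-only linker 4
          n_w = 2L * n_la + 4L * n_lw + rest_w,
          n_a2 = n_la + rest_a2,
          n_dimers = 3L * x,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write or read a species table as CSV
#'
#' @param species Data frame from [enumerate_species()].
#' @param path Output/input file path.
#' @return `write_species_csv()` returns `path` invisibly;
#'   `read_species_csv()` returns the species data frame.
#' @export
write_species_csv <- function(species, path) {
  utils::write.csv(species, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_species_csv
#' @export
read_species_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
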