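Package: mwcens
Title: Statistical-Mechanics Ensemble Model of Chemoreceptor Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equilibrium ensemble model of bacterial chemotaxis receptor
    clusters in which trimers of receptor dimers are connected by
    CheW/CheA2 (and optionally CheW-only) linkers. Implements the
    two-state Monod-Wyman-Changeux free energies, grand-canonical
    enumeration of complex species with partially developed linker rest
    groups, a density-constrained chemical potential solved by Brent's
    method, dose-response and Hill-coefficient analysis across CheA/CheW
    expression levels, multi-start parameter fitting against FRET-like
    dose-response data, and a seedable synthetic-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
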