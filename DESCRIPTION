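Package: shdikit
Title: Construction of Subnational Human Development Index Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build complete subnational human development databases
    from gappy regional indicator panels and a complete national reference
    series. Implements goalpost normalization and geometric-mean aggregation
    of the health, education and income dimensions; population-weighted
    multiplicative scaling that anchors subnational indicator means to
    national values; two-step interpolation/extrapolation gap filling with
    per-cell quality flags; regression bridges estimating life expectancy
    from under-five mortality and log income from an asset wealth index;
    a synthetic multi-country panel generator for testing; and a simulated
    inter/extrapolation relative-error study summarized as ventiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
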