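Package: stressorscape
Title: Spatiotemporal Association Analysis of Meteorological and
    Air-Pollution Stressors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how daily meteorological variables
    (temperature, precipitation, vapor pressure, UV radiation) and air
    pollutants (ozone, nitrogen dioxide, fine and coarse particulate
    matter) co-vary in time and space over a set of administrative areas.
    Provides derived-variable construction (Magnus vapor pressure from
    dewpoint, UV energy-to-power conversion, population-density
    categories), pooled and stratified Pearson correlation matrices with
    a correlation-strength taxonomy, lagged auto- and cross-correlation
    at day and month resolution, polygon-contiguity spatial weights,
    local Moran's I with conditional-permutation inference and
    hot/cold-spot (LISA) classification, stratum summary tables, a
    seeded synthetic lattice generator that emulates the covariation
    structure of regional reanalysis panels, and a reproducible
    end-to-end pipeline writing a checksummed report bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
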