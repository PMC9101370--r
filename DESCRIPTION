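Package: etmap
Title: UAV Thermal Imagery to Evapotranspiration Maps via a Two-Source Energy Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processing chain turning pseudo-colored UAV thermal snapshots into
    evapotranspiration (latent heat flux) maps. Decodes palette-encoded thermal
    images back to physical temperature, rescales flights to a common temperature
    range, geotags camera trigger events against post-processed kinematic (PPK)
    GNSS tracks, prepares leaf area index and vegetation cover rasters from RGB
    orthomosaics, solves a two-source (soil + canopy) energy balance with
    Priestley-Taylor initialization per pixel, and validates modelled latent heat
    against eddy-covariance measurements averaged over a footprint disk. Includes
    a synthetic-flight generator so the full pipeline is testable end to end
    without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    generics,
    withr,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    geosphere,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
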