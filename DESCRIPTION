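Package: soilcoda
Title: Compositional Analysis of Soil Pollution Health-Risk Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screening-level human health risk assessment for persistent
    organic pollutants (PAHs, PCBs, organochlorine pesticides) in soils:
    risk-based soil screening levels for ingestion, dermal and inhalation
    exposure, hazard quotients and the additive hazard index, and the
    relative contribution of each compound to the summed risk.  The
    contribution vectors are compositions, and the package supplies the
    Aitchison-geometry toolkit used to explore them: closure, perturbation,
    centred and isometric log-ratio transforms, variation matrix, robust
    principal component analysis with compositional biplots, principal
    coordinate analysis on Aitchison distances, fuzzy c-means clustering of
    pollution profiles, and ternary-diagram coordinates.  A synthetic survey
    generator with latent pollution archetypes and left-censored
    concentrations supports testing the full pipeline without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
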