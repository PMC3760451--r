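Package: phytosol
Title: Solubility Parameters and Surface Energetics of Plant Surfaces and
    Agrochemicals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Thermodynamic screening of agrochemical-plant surface
    interactions. Computes Hansen-type solubility parameter components
    (dispersion, polar, hydrogen bonding) for molecules from van
    Krevelen-Hoftyzer structural group contributions; derives van
    Oss-Chaudhury-Good surface free energy components, polarity, work of
    adhesion and a surface solubility parameter from three-liquid contact
    angle measurements; and screens chemical-surface affinity by
    solubility parameter differences with Greenhalgh miscibility
    thresholds. Ships a validated registry of epicuticular waxes, cutin
    monomers, cell wall polysaccharide monomers and agrochemicals,
    cutin esterification variants, and a cuticle solubility gradient
    report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
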