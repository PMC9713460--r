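Package: drivesim
Title: CRISPR/Cas9 Homing Gene-Drive Assessment and Population Simulation for Aedes aegypti
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing single-locus CRISPR/Cas9 homing gene drives in
    the mosquito Aedes aegypti from single-generation cross data. Estimates
    sex-specific cutting, homing and resistance-allele (gene-drive-blocking
    indel, GDBI) formation rates from pooled marker-inheritance counts,
    estimates maternal Cas9 ribonucleoprotein deposition from
    trans-heterozygous balancer crosses, builds the corresponding
    mother-by-father-by-offspring inheritance cube with a merged cost-free
    resistance allele, summarises amplicon-sequencing indel classifications,
    and simulates single-release population-replacement scenarios with a
    daily, stage-structured, density-dependent stochastic mosquito model.
    Includes a synthetic-data generator emulating binomially sampled marker
    inheritance, GDBI accrual and amplicon read classification so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
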