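Package: covex
Title: Patient-Specific Cancer Driver Modules by Coordinating Coverage and
    Exclusivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate cancer driver modules from a binary
    patient-by-gene somatic mutation matrix and one or more protein
    interaction networks.  Candidate gene modules are discovered by exact
    optimization of the Dendrix weight on local influence networks derived
    from an insulated heat-diffusion process, filtered by a combinatorial
    coverage-times-exclusivity score (CovEx) against an empirical null of
    random connected subnetworks, and reduced to patient-specific crucial
    modules with a greedy minimum set cover.  Predictions from several
    networks and parameter settings are combined into consensus modules.
    Includes a synthetic benchmark generator with planted mutually exclusive
    modules for end-to-end evaluation.
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
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
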