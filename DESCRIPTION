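Package: neonicr
Title: Neonicotinoid Seed-Treatment Use Mapping and Censored Wetland
    Residue Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the spatial footprint of neonicotinoid
    seed treatments on gridded cropland and for analysing censored
    (below limit-of-quantification) neonicotinoid concentrations measured
    repeatedly in prairie pothole wetlands. Builds per-hectare
    application-rate rasters from a crop-classification grid and a
    treatment registry, aggregates them to quarter-section parcels and
    rate categories, summarises recovery-corrected residue panels into
    detection frequencies and crop-by-season statistics, fits Gaussian
    linear mixed models of log total neonicotinoid concentration with
    crop-season interaction contrasts under Dunn-Sidak correction, and
    simulates crop landscapes and residue panels with known ground truth
    so every stage is testable without confidential inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    lme4,
    lmerTest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
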