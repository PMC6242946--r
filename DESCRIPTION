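Package: epiclonal
Title: Methylation-Sensitive AFLP Epigenotyping and Ordinal Bud-Set
    Phenology for Clonal Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for DNA-methylation variation and
    transgenerational phenology in clonal plant collections. Scores
    dual-enzyme (HpaII/MspI) methylation-sensitive AFLP fragment profiles
    into binary epigenotypes with per-primer error thresholds, quantifies
    epigenetic diversity and structure (Shannon index, principal
    coordinate analysis, distance-based AMOVA with permutation Phi-ST,
    Mantel tests against geography), identifies clone membership from
    multilocus microsatellite genotypes, fits a cumulative link mixed
    model with donor and ramet random intercepts by Laplace approximation
    to ordinal bud-set scores, derives per-donor D50% bud-set timing, and
    tests per-epilocus associations with climate under
    Benjamini-Hochberg false-discovery-rate control. Includes synthetic
    data generators that emulate the statistical structure of every
    input, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    lme4,
    vegan,
    optparse
Config/testthat/edition: 3
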