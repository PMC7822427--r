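Package: rootstress
Title: Root-Type Morphology Analysis Under Single and Combined Abiotic Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for maize root-system-architecture trait
    tables from factorial single and combined abiotic stress experiments
    (drought, heat, and their combination). Provides derivation of root
    length ratio and its morphological components, one-way ANOVA with
    Tukey multiple comparisons and compact letter displays, classification
    of combined-stress responses as additive, synergistic or antagonistic
    under a multiplicative-risk additive expectation, permutational
    multivariate analysis of variance (PERMANOVA) with pairwise
    FDR-corrected contrasts, sparse partial least squares discriminant
    analysis (sPLS-DA) with cross-validated component and variable
    selection, and a seeded synthetic-data generator calibrated to
    published per-treatment trait means and standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mixOmics,
    withr
Config/testthat/edition: 3
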