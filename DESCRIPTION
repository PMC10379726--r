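Package: fctomics
Title: Longitudinal Fecal Community Typing and Multi-Omics Analysis for
    Infant Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal infant fecal microbiome and
    metabolome studies with two treatment arms. Implements Dirichlet
    multinomial mixture (DMM) community typing with Laplace model-evidence
    selection, age-binned fecal community type (FCT) transition networks,
    time-to-transition survival analysis (Kaplan-Meier, log-rank, Cox),
    rank-based group comparisons with Cliff's delta effect sizes, PLS/PLS-DA
    metabolite modelling with VIP-based discriminant selection, bile-acid
    conjugation ratios, and FDR-controlled interdomain (KO-metabolite)
    Kendall correlation. Ships a synthetic two-arm cohort generator so the
    whole pipeline is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    picante,
    vegan,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
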