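Package: pharmatrace
Title: Provenance Tracing of Falsified Medicines from Pharmabiome and
    Chemometric Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to trace the manufacturing origin of (simulated) falsified
    medicine tablets from the trace environmental DNA they accrue during
    production (the "pharmabiome") and from DART mass-spectrometry chemical
    fingerprints. Implements negative-control and excipient decontamination of
    ASV count tables, iterative rarefaction, alpha and beta diversity testing
    (Kruskal-Wallis with Dunn post-hoc tests, PERMANOVA, dispersion
    homogeneity), differential-abundance analysis with poscounts
    normalisation, log2-fold ratios, Wald tests and Benjamini-Hochberg
    correction, origin classification by discriminant analysis of principal
    components (DAPC) and kernel discriminant analysis (KDA) with
    leave-one-out cross-validation, DART-MS spectrum preprocessing and
    Fisher-ratio feature selection, and a reference-free geolocation workflow
    that resolves origin-informative ASVs to taxa by the
    largest-percent-identity rule and builds unified species-distribution
    maps from point occurrences and botanical-region presences. A
    synthetic-data generator with known ground truth emulates the two-site
    tableting study design for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    tools,
    vegan,
    yaml,
    jsonlite
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
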