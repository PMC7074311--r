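Package: seedqtl
Title: QTL Mapping and Marker-Assisted Selection for Grapevine Seedlessness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of the genetic architecture of
    stenospermocarpic seedlessness in a bi-parental grapevine F1 cross.
    Provides a pseudo-testcross population simulator (Haldane meiosis, a
    configurable multi-QTL architecture with a partially dominant major
    locus, multi-season phenotypes), descriptive phenotype statistics and
    REML/BLUP estimation across seasons, Haley-Knott regression interval
    mapping with automatic cofactor selection, multiple-QTL mapping and
    permutation-based LOD thresholds, a greedy multi-locus ideotype
    stacking model for assisted selection, and binary diagnostic-marker
    evaluation (sensitivity, specificity, predictive values, Matthews
    correlation, Fisher's exact test, polymorphism information content).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
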