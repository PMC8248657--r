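Package: hdwtrules
Title: Class Association Rules Between Non-Motor Factors and Weight Loss
    in Premanifest Huntington's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the association between non-motor clinical
    factors and severe weight loss in premanifest Huntington's disease.
    Implements longitudinal percentage weight-change computation, expert
    knowledge-based ordinal categorization of clinical scores, class
    association rule mining (Apriori with a weight-category consequent
    constraint) scored with support, confidence, lift, conviction,
    chi-square and an odds-ratio strength measure plus redundant-rule
    elimination, self-organizing-map pattern summaries, and mutual
    information and conditional entropy dependence analysis. A seeded
    synthetic cohort generator with plantable antecedent-to-weight-category
    dependencies makes the whole pipeline testable without access to
    restricted clinical registries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
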