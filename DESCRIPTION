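Package: dsfusion
Title: Disulfide Bond Topology Determination by Dempster-Shafer Evidence Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Determines protein disulfide (S-S) bond topology by fusing
    bond-level evidence from heterogeneous predictors: tandem mass
    spectrometry fragment-match scoring, SVM sequence-based prediction with
    Platt-calibrated beliefs, and cysteine separation profile matching
    against an annotated reference database. Evidence is combined within an
    extended Dempster-Shafer framework offering four combination rules
    (Dempster, Yager, Campos, Shafer discount-and-average), a belief
    assignment function over consistent subsets of candidate bonds, and
    data-driven discounting of unreliable sources. Includes performance
    metrics, fixture data sets, and a seeded synthetic-evidence generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
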