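Package: sigddi
Title: Polypharmacy Side-Effect Prediction from Drug-Induced Expression Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts polypharmacy side effects of drug pairs from drug-induced
    transcriptional signatures. A feature-generation network maps compound
    structure (Morgan fingerprints) and physicochemical properties to a
    978-landmark-gene differential-expression signature, and a pair-conditional
    gated encoder with a translating-embedding score per side effect ranks
    drug-drug interaction triplets under a margin loss. Includes cold-start
    evaluation splits (unseen interaction, one-unseen and both-unseen drugs),
    per-side-effect ranking metrics, a permutation test for external validation,
    gene-level gate attention for interpretability, and synthetic-world
    generators that plant the assumed statistical structure for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ranger,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
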