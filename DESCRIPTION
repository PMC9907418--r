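Package: annoval
Title: Consensus, Agreement and Reward Valuation for Multi-Annotator Image Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating multi-annotator, multi-label annotation
    studies such as chest-radiograph reader studies. Builds complete
    annotator-by-image-by-label annotation sheets from record-level CSV files,
    derives a majority-vote pseudo ground truth, computes agreement statistics
    (unanimity fraction, Cohen's and Fleiss's kappa, pairwise discrepancy
    matrices), screens annotators against an AI reference with a kappa-based
    quality gate, and allocates a fixed token budget across annotators from
    per-cell data values, per-label task values, normalized labeling-time
    means, and contribution credits. Includes a seeded synthetic reader-study
    generator and an append-only SHA-256 hash-chained activity ledger with
    integrity verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    digest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    openssl,
    e1071,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
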