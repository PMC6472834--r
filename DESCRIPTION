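Package: taxclean
Title: Score-Aware Comparative Metagenomics with Robust Contamination Removal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of read-level taxonomic classifier output
    (Centrifuge, Kraken, CLARK and generic CSV/TSV/SSV formats) for
    comparative shotgun metagenomics. Builds per-sample scored taxonomic
    trees on the NCBI Taxonomy, folds them to a rank of interest with a
    weighted-average score recursion, derives control-subtracted,
    exclusive and shared sample sets, and removes reagent and crossover
    contamination with a robust algorithm based on the median and the Qn
    scale estimator plus an order-of-magnitude test against negative
    controls. Includes a mock classifier-output generator and a
    sensitivity/specificity harness to validate the removal algorithm,
    deterministic tabular/Krona-text/JSON writers, and an end-to-end
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    parallel,
    tools,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
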