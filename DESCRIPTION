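Package: permenrich
Title: Permutation Enrichment of Transcription-Factor Targets and Gene-Set Overlap Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo permutation tests for transcription-factor (TF) target
    enrichment in query gene sets, using ChIP-seq derived target lists with peak
    scores. For each TF the observed target count and peak-score mass inside a
    query set are compared against random draws of the same size from a declared
    gene universe, yielding dual permutation p-values (count and score) with
    Bonferroni and Benjamini-Hochberg adjustment, including partial-family
    step-up adjustment when only the smallest p-values of a larger family are
    in hand. Also provides exact hypergeometric two-set overlap statistics with
    over/under-representation folds, multi-set Venn partitioning, GMT gene-set
    and TF target-table readers/writers, and a synthetic-data generator with
    planted enrichment signal for benchmarking. A command-line interface wires
    the subcommands together with reproducible manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
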