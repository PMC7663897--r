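Package: triplexpot
Title: Predicting DNA:RNA Triplex-Forming Potential from Sequence Composition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting which long non-coding RNAs are most likely to
    form DNA:RNA triplexes in practice, and the triplex-forming potential of
    DNA sites, from nucleotide sequence composition alone. Sequences are
    represented by a fixed 90-dimensional vector of overlapping k-mer
    frequencies (k = 1..3) and log-odds k-mer composition scores (k = 1..6)
    and classified by a small two-layer one-dimensional convolutional neural
    network implemented in the package. Includes the class-imbalance handling
    used for training (random negative down-sampling and weighted bagging of
    the minority positive subtype), stratified cross-validation and
    leave-gene-out evaluation harnesses, an approximate greedy redundancy
    filter, a synthetic sequence generator for end-to-end testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
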