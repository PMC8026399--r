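Package: seedhit
Title: Sensitive Spaced-Seed Protein Homology Search with Double Indexing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of a sensitive seed-and-extend
    protein aligner. Both query and reference sequences are indexed with
    sets of multiple spaced seeds and matching seeds are found by a
    recursive radix hash join (double indexing). A cascade of filter
    stages (48-letter Hamming window, x-drop ungapped extension,
    leftmost-seed redundancy filter, gapped-score heuristic) gradually
    eliminates spurious hits before diagonal-segment chaining determines
    the band geometry for a banded affine Smith-Waterman extension.
    Includes frameshift-aware translated (blastx-style) search,
    probabilistic tandem-repeat (tantan-style) soft masking, a file-based
    fault-tolerant distributed work protocol runnable with many local
    processes, and an evaluation harness (synthetic protein-family
    generator, AUC1 and ROC statistics) for homology-detection
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    parallel,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
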