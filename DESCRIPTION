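Package: motifgram
Title: Discriminative n-Gram Mining for Class-Labeled Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines short class-specific peptide motifs from protein sequence
    sets grouped into classes (subcellular locations, enzyme families, and
    similar groupings). n-grams of sizes 4 to 8 are extracted exhaustively,
    pooled with their single-position BLOSUM62-positive variants, normalized
    across unbalanced classes by a TF-IDF-style dampening factor, and selected
    by a discriminative ratio comparing each n-gram's best class frequency to
    the mean of its second and third highest. Selected n-grams are cleaned of
    substrings, mapped back onto sequences, merged into contiguous motifs, and
    optionally used to mask non-discriminative regions. Includes converters
    for PROSITE- and NLSdb-dialect patterns to regular expressions, coverage
    and confusion-matrix/ROC evaluation, and a seeded synthetic-data generator
    with planted, point-mutated, class-exclusive motifs for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
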