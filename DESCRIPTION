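Package: ednacnn
Title: Convolutional Neural Network Annotation of eDNA Metabarcoding Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains convolutional neural network classifiers on reference
    barcode databases (short mitochondrial amplicons such as the ~60 bp 12S
    "teleo" fragment) and applies them directly to raw Illumina FASTQ reads
    to produce per-sample species read-count tables. Includes augmentation-
    driven training (class balancing, substitution noise, random indels,
    primer/tag decoration, reverse complements), softmax rejection
    thresholding with F-beta threshold selection, exact-match hash-table
    demultiplexing, a synthetic read simulator with ground truth, and
    community-composition agreement statistics (Kendall tau-b, Cohen's
    kappa, Bray-Curtis dissimilarity, three-way species overlap).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    e1071,
    optparse
Config/testthat/edition: 3
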