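Package: splitADT
Title: Split-Pool DNA-Barcoded Antibody Sequencing Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sequencing-based single-cell protein quantification by
    split-pool combinatorial indexing of DNA-barcoded antibodies. Provides a
    forward simulator that emits paired-end FASTQ reads with ground truth
    (multi-sample hashtagged cell populations, spike-in control cells,
    split-pool well assignment, ligation and blocking failure, PCR
    duplication, sequencing error), a demultiplexer that reconstructs single
    cells from tripartite well barcodes with Hamming-distance error
    correction and directional UMI collapse, and an analysis layer covering
    the centered log-ratio transform, Poisson barcode-collision loading
    rules, combinatorial hashtag sample decoding, spike-in control QC,
    PCA/k-means/t-SNE, and flow-style hierarchical gating.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    Matrix,
    methods,
    Rtsne,
    stats,
    tools,
    utils,
    yaml
Suggests:
    cluster,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
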