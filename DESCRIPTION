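Package: hiscl
Title: Droplet-Based Single-Cell Labeling: Barcode Design, Run Simulation,
    Demultiplexing and Correlation Clustering
Version: 0.1.0
Authors@R: person("Dana", "Levy", email = "dana.levy@example.org",
    role = c("aut", "cre"))
Description: Tools for drop-based single-cell RNA-seq labeling workflows in
    which each cell-bearing droplet is fused with a droplet carrying many
    copies of one DNA barcode.  Covers design of barcode libraries under
    composition rules with a minimum pairwise Hamming distance, closed-form
    and Monte-Carlo statistics of Poisson droplet loading (doublet rates,
    barcode collisions, collection throughput), a synthetic droplet-run
    simulator emitting paired FASTQ with full ground truth, demultiplexing
    of paired reads into a barcodes-by-genes unique-transcript counts
    matrix, Poisson-background cell calling, barnyard (human/mouse)
    crosstalk estimation, and unsupervised two-way clustering of
    single-cell profiles by leave-one-out correlation K-means.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
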