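Package: lpiFuse
Title: Predicting lncRNA-Protein Interactions by Similarity Kernel Fusion
    and Laplacian Regularized Least Squares
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A semi-supervised bipartite link predictor for lncRNA-protein
    interaction networks. Three similarity kernels per molecular space
    (Gaussian interaction-profile kernels from the adjacency matrix,
    expression-correlation or sequence-alignment kernels, and linear
    neighborhood similarity over sequence-derived features) are integrated
    by an iterative similarity kernel fusion (cross-diffusion) procedure,
    and unknown lncRNA-protein pairs are scored with Laplacian regularized
    least squares on each fused space. Includes readers for the standard
    input artifacts (interaction pair lists, FASTA sequences, expression
    tables, BLAST tabular bit scores), a synthetic-data generator with
    planted low-rank structure for end-to-end testing, three
    cross-validation protocols (pairwise, novel-lncRNA, novel-protein)
    with AUROC/AUPR/F1 reporting, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, Biostrings, MASS
Suggests: testthat (>= 3.0.0), pROC, jsonlite, optparse, withr
Config/testthat/edition: 3
biocViews: NetworkInference, SystemsBiology, Transcriptomics
RoxygenNote: 7.3.3
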