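Package: rescuemap
Title: Trajectory Classification and Chromosomal Neighborhood Analysis for
    Evolutionary Rescue Experiments
Version: 0.1.0
Authors@R:
    person("Magda", "Reiter", email = "mreiter@example.org", role = c("aut", "cre"))
Description: Tools for analysing evolutionary-rescue experiments that probe
    how the chromosomal neighborhood of a gene under selection shapes its
    adaptive potential. Classifies daily plate-reader trajectories (OD600,
    YFP, CFP) into rescue and fluorescence phenotypes, detects transient
    gene-amplification signatures, computes selection-design quantities
    (MIC, geometric drug schedules, generations under serial dilution),
    quantifies gene copy number from qPCR by efficiency-corrected delta-delta-Cq,
    finds direct repeats with Hamming tolerance, classifies per-gene adaptive
    potential from genome annotation (Rho-terminated upstream transcripts,
    deletion-co-optable promoters, flanking duplicates), and provides exact
    r-by-c contingency and seeded permutation tests. A stochastic
    serial-transfer rescue simulator generates synthetic plates with known
    ground truth so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomeInfoDb,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
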