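Package: rohsim
Title: Simulation Benchmarking of Runs-of-Homozygosity Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how sequencing depth, read length, reference
    genome contiguity and reference divergence bias the detection of runs of
    homozygosity (ROH) and the inbreeding coefficient F_ROH. Generates
    synthetic diploid genomes with planted ROH at specified inbreeding
    levels, builds per-individual haplotypes, simulates error-free paired-end
    reads with an origin-aware pileup genotype caller (explicit allele-dropout
    model), degrades reference contiguity along a contig-N50 ladder,
    reimplements the two-step PLINK ROH procedure (LD pruning plus
    sliding-window homozygosity scan) together with a simplified two-state
    hidden Markov model caller, applies gap-merging and length filtering, and
    summarises recovery with F_ROH error ratios, SNP error ratios,
    length-class tables and detection ratios across benchmark sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
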