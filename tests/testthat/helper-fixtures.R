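# small deterministic fixtures shared across test files

tiny_cfg <- function(seed = 1L, targets = c(0.12, 0.35)) {
  sim_config(n_contigs = 1L, contig_len = 6e6, target_f_roh_levels = targets,
             seed = seed)
}

# construct a roh_calls object directly from genotype/position vectors
make_calls <- function(gt, pos, contig = "chr1", individual = "indT") {
  contig <- rep(contig, length.out = length(pos))
  o <- order(contig, pos)
  structure(list(individual = individual,
                 sites = data.frame(contig = contig[o], pos = pos[o],
                                    stringsAsFactors = FALSE),
                 gt = as.integer(gt)[o], dp = rep(10L, length(pos)),
                 call_config = NULL),
            class = "roh_calls")
}

make_segs <- function(start, end, contig = "chr1", iid = "indT",
                      n_snps = rep(10L, length(start)), caller = "window") {
  n <- length(start)
  df <- data.frame(iid = rep(iid, length.out = n),
                   contig = rep(contig, length.out = n),
                   start = start, end = end, n_snps = n_snps,
                   caller = rep(caller, length.out = n),
                   stringsAsFactors = FALSE)
  class(df) <- c("roh_segments", "data.frame")
  df
}

# random genotype vector with controlled het/missing sprinkling
random_gt <- function(m, p_het = 0.15, p_miss = 0.1, p_hom_alt = 0.2) {
  g <- sample(c(0L, 2L), m, replace = TRUE, prob = c(1 - p_hom_alt, p_hom_alt))
  g[runif(m) < p_het] <- 1L
  g[runif(m) < p_miss] <- NA_integer_
  g
}
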