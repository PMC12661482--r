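test_that("read counts implement diploid depth accounting", {
  ref <- roh_reference(c(chr1 = strrep("ACGT", 250000)))  # 1 Mb
  hp <- structure(list(hapA = ref$contigs, hapB = ref$contigs,
                       individual = "s1"), class = "roh_haplotypes")
  reads <- simulate_reads(hp, 10, read_len = 100L, seed = 2L)
  # round(depth * len / (2*2*read_len)) pairs per haplotype
  expect_length(reads$frags$chr1$A$start, 25000L)
  expect_length(reads$frags$chr1$B$start, 25000L)
  expect_equal(n_pairs(reads), 50000L)
  # pooled read bases / genome length = diploid depth
  expect_equal(realized_depth(reads, hp), 10)
  # determinism
  reads2 <- simulate_reads(hp, 10, read_len = 100L, seed = 2L)
  expect_identical(reads$frags, reads2$frags)
  expect_error(simulate_reads(hp, 0), "depth")
  expect_error(simulate_reads(hp, 5, read_len = 600L), "frag_mean")
})

test_that("contigs shorter than the fragment length are skipped with warning", {
  hp <- structure(list(hapA = c(chr1 = strrep("A", 12000), chrS = strrep("A", 300)),
                       hapB = c(chr1 = strrep("A", 12000), chrS = strrep("A", 300)),
                       individual = "s1"), class = "roh_haplotypes")
  expect_warning(reads <- simulate_reads(hp, 5, read_len = 100L, seed = 1L),
                 "chrS")
  expect_null(reads$frags$chrS)
})

test_that("error-free mates are exact substrings of their source haplotype", {
  set.seed(3)
  seqA <- paste(sample(c("A", "C", "G", "T"), 12000, TRUE), collapse = "")
  seqB <- paste(sample(c("A", "C", "G", "T"), 12000, TRUE), collapse = "")
  hp <- structure(list(hapA = c(chr1 = seqA), hapB = c(chr1 = seqB),
                       individual = "s1"), class = "roh_haplotypes")
  reads <- simulate_reads(hp, 3, read_len = 50L, seed = 9L)
  dir <- withr::local_tempdir()
  fq <- write_fastq(reads, hp, file.path(dir, "s1"))
  l1 <- readLines(fq[1]); l2 <- readLines(fq[2])
  ids <- sub("^@", "", sub("/1$", "", l1[seq(1, length(l1), 4)]))
  m1 <- l1[seq(2, length(l1), 4)]
  m2 <- l2[seq(2, length(l2), 4)]
  parts <- do.call(rbind, strsplit(ids, "|", fixed = TRUE))
  for (i in seq_len(nrow(parts))) {
    src <- if (parts[i, 2] == "A") seqA else seqB
    st <- as.integer(parts[i, 4])
    expect_equal(m1[i], substring(src, st, st + 49L))
  }
  # mate 2 is the reverse complement of the fragment's other end
  idx <- match(ids[1], sprintf("s1|A|chr1|%d|%d", reads$frags$chr1$A$start,
                               seq_along(reads$frags$chr1$A$start)))
  if (!is.na(idx)) {
    fl <- reads$frags$chr1$A$len[idx]
    st <- reads$frags$chr1$A$start[idx]
    frag_end <- substring(seqA, st + fl - 50L, st + fl - 1L)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag_end)))
    expect_equal(m2[1], rc)
  }
})

test_that("per-site depth matches the Poisson expectation", {
  ref <- roh_reference(c(chr1 = strrep("ACGT", 50000)))  # 200 kb
  hp <- structure(list(hapA = ref$contigs, hapB = ref$contigs,
                       individual = "s1"), class = "roh_haplotypes")
  reads <- simulate_reads(hp, 20, read_len = 100L, seed = 5L)
  sites <- data.frame(contig = "chr1", pos = seq(2000L, 198000L, by = 200L),
                      ref = "A", alt = "C")
  sites$ref <- ref_base_at(ref$contigs[[1]], sites$pos)
  sites$alt <- ifelse(sites$ref == "A", "C", "A")
  cg <- pileup_call(reads, sites, hp, call_config(), seed = 1L)
  md <- mean(cg$dp)
  se <- sqrt(20 / nrow(sites))   # Poisson approximation
  expect_lt(abs(md - 20), 3 * se + 0.2)
})

test_that("subsample_depth is Bernoulli thinning with determinism", {
  ref <- roh_reference(c(chr1 = strrep("ACGT", 250000)))
  hp <- structure(list(hapA = ref$contigs, hapB = ref$contigs,
                       individual = "s1"), class = "roh_haplotypes")
  reads <- simulate_reads(hp, 10, read_len = 100L, seed = 2L)
  expect_identical(subsample_depth(reads, 1, seed = 1L), reads)
  half <- subsample_depth(reads, 0.5, seed = 1L)
  # kept count within the binomial 99% CI of 25,000 of 50,000
  expect_lt(abs(n_pairs(half) - 25000), 2.58 * sqrt(50000 * 0.25) + 1)
  expect_equal(half$depth, 5)
  half2 <- subsample_depth(reads, 0.5, seed = 1L)
  expect_identical(half$frags, half2$frags)
  expect_error(subsample_depth(reads, 0), "fraction")
  expect_error(subsample_depth(reads, 1.2), "fraction")
})

test_that("pileup genotype thresholds behave site-wise", {
  # two haplotypes differing at pos 50: A carries ref 'A', B carries alt 'C'
  base <- strrep("A", 1000)
  hapB <- paste0(substring(base, 1, 49), "C", substring(base, 51, 1000))
  hp <- structure(list(hapA = c(chr1 = base), hapB = c(chr1 = hapB),
                       individual = "s1"), class = "roh_haplotypes")
  sites <- data.frame(contig = "chr1", pos = 50L, ref = "A", alt = "C")
  mk_reads <- function(nA, nB) {
    structure(list(individual = "s1", read_len = 100L, frag_mean = 500,
                   frag_sd = 50, err_rate = 0, depth = 1,
                   frags = list(chr1 = list(
                     A = list(start = rep(1L, nA), len = rep(500L, nA)),
                     B = list(start = rep(1L, nB), len = rep(500L, nB))))),
              class = "roh_reads")
  }
  # both alleles seen -> het (50 reads each: certain)
  cg <- pileup_call(mk_reads(50, 50), sites, hp, call_config(), seed = 1L)
  expect_equal(cg$gt, 1L)
  expect_equal(cg$dp, 100L)
  # a single read with min_depth 2 -> missing
  cg1 <- pileup_call(mk_reads(1, 0), sites, hp, call_config(min_depth = 2),
                     seed = 1L)
  expect_true(is.na(cg1$gt))
  # only haplotype-A reads -> hom-ref; only B -> hom-alt
  expect_equal(pileup_call(mk_reads(3, 0), sites, hp, call_config(), 1L)$gt, 0L)
  expect_equal(pileup_call(mk_reads(0, 3), sites, hp, call_config(), 1L)$gt, 2L)
  # no reads -> missing
  expect_true(is.na(pileup_call(mk_reads(0, 0), sites, hp, call_config(), 1L)$gt))
  # site outside the contig errors
  bad <- data.frame(contig = "chr1", pos = 2000L, ref = "A", alt = "C")
  expect_error(pileup_call(mk_reads(1, 1), bad, hp, call_config(), 1L),
               "bounds")
})

test_that("pileup converges to truth at high depth", {
  cfg <- sim_config(n_contigs = 1L, contig_len = 2e6,
                    target_f_roh_levels = 0.3, seed = 17L)
  ref <- make_reference(cfg)
  pop <- plant_population(ref, cfg)
  hp <- build_haplotypes(ref, pop$variants, "ind01", seed = 1L)
  reads <- simulate_reads(hp, 100, seed = 3L)
  cg <- pileup_call(reads, pop$variants$sites, hp, call_config(), seed = 2L)
  err <- snp_error_ratio(cg, pop$variants, "ind01")
  expect_lt(err$error_ratio, 1e-3)
  expect_lt(err$missing_rate, 1e-3)
  # haplotype balance: A-reads within binomial CI of half the total
  nA <- length(reads$frags$chr1$A$start)
  nTot <- n_pairs(reads)
  expect_lt(abs(nA - nTot / 2), 3 * sqrt(nTot * 0.25) + 1)
})

test_that("snp_error_ratio counts mismatches over truth sites", {
  sites <- data.frame(contig = "chr1", pos = 1:12 * 10L,
                      ref = "A", alt = "C")
  tg <- c(rep(1L, 6), rep(2L, 4), 0L, 0L)   # 10 truth variant sites
  vs <- roh_variants(sites, matrix(tg, ncol = 1, dimnames = list(NULL, "s1")))
  cg <- calls_from_truth(vs, "s1")
  expect_equal(snp_error_ratio(cg, vs, "s1")$error_ratio, 0)
  cg$gt[c(1, 7)] <- c(0L, 1L)               # two miscalls
  cg$gt[2] <- NA_integer_                   # one missing truth site
  r <- snp_error_ratio(cg, vs, "s1")
  expect_equal(r$error_ratio, 0.2)
  expect_equal(r$missing_rate, 0.1)
  expect_equal(r$n_truth_sites, 10L)
  expect_error(snp_error_ratio(cg, vs, "nope"), "not present")
})
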