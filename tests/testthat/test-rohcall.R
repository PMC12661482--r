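test_that("ld_prune removes later sites of correlated pairs", {
  # identical dosage profiles -> r2 = 1 -> the later site is removed
  dose <- c(0L, 1L, 2L, 0L, 1L, 2L, 1L, 0L)   # 8 individuals
  geno <- rbind(site1 = dose, site2 = dose)
  dimnames(geno) <- list(NULL, paste0("i", 1:8))
  sites <- data.frame(contig = "chr1", pos = c(100L, 200L),
                      ref = "A", alt = "C")
  vs <- roh_variants(sites, geno)
  expect_equal(ld_prune(vs, roh_params(prune_r2 = 0.8)), 1L)
  # orthogonal dosages (r = 0) are all kept
  g3 <- rbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
  dimnames(g3) <- list(NULL, paste0("i", 1:4))
  vs3 <- roh_variants(data.frame(contig = "chr1", pos = c(100L, 200L),
                                 ref = "A", alt = "C"), g3)
  expect_equal(ld_prune(vs3, roh_params(prune_r2 = 0.5)), c(1L, 2L))
  # pruning disabled or single individual: no-op
  expect_equal(ld_prune(vs, roh_params()), c(1L, 2L))
  vs1 <- roh_variants(sites, matrix(c(0L, 0L), 2, 1,
                                    dimnames = list(NULL, "a")))
  expect_warning(keep <- ld_prune(vs1, roh_params(prune_r2 = 0.8)), "skipped")
  expect_equal(keep, c(1L, 2L))
})

test_that("ld_prune matches the exhaustive-pair greedy oracle", {
  set.seed(42)
  for (case in 1:60) {
    m <- sample(5:30, 1)
    n <- sample(3:8, 1)
    geno <- matrix(sample(c(0L, 1L, 2L, NA), m * n, TRUE,
                          prob = c(.4, .3, .25, .05)), m, n)
    colnames(geno) <- paste0("i", seq_len(n))
    pos <- sort(sample(1e6, m))
    vs <- roh_variants(data.frame(contig = "chr1", pos = pos,
                                  ref = "A", alt = "C"), geno)
    w <- sample(3:12, 1); st <- sample(1:3, 1); r2 <- runif(1, 0.2, 0.95)
    p <- roh_params(prune_window = w, prune_step = st, prune_r2 = r2)
    expect_equal(ld_prune(vs, p), oracle_ld_prune(geno, pos, w, st, r2),
                 info = sprintf("case %d", case))
  }
})

test_that("window scan calls obvious homozygous runs and rejects het tracts", {
  # 300 hom calls evenly spaced over 3 Mb -> one segment first->last site
  pos <- (1:300) * 10000L
  cg <- make_calls(rep(0L, 300), pos)
  segs <- call_roh_window(cg, roh_params())
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start, pos[1] - 1)
  expect_equal(segs$end, as.numeric(pos[300]))
  expect_equal(segs$n_snps, 300L)
  # alternating het/hom: every window fails
  cg2 <- make_calls(rep(c(0L, 1L), 150), pos)
  expect_equal(nrow(call_roh_window(cg2, roh_params())), 0L)
  # a contig with fewer sites than the window is skipped with a warning
  cg3 <- make_calls(rep(0L, 10), (1:10) * 1000L)
  expect_warning(s3 <- call_roh_window(cg3, roh_params()), "skipped")
  expect_equal(nrow(s3), 0L)
})

test_that("window scan equals the exhaustive-window oracle on random instances", {
  set.seed(7)
  for (case in 1:120) {
    m <- sample(30:200, 1)
    pos <- sort(sample.int(3e6, m))
    gt <- random_gt(m, p_het = runif(1, 0, 0.25), p_miss = runif(1, 0, 0.15))
    p <- roh_params(window_snps = sample(c(5L, 10L, 20L, 50L), 1),
                    min_kb = sample(c(50, 200, 500), 1),
                    min_snps = sample(c(5L, 20L, 60L), 1),
                    window_het_allow = sample(0:2, 1),
                    window_missing_allow = sample(c(2L, 5L), 1),
                    window_hit_threshold = runif(1, 0.03, 0.6),
                    max_internal_gap_kb = sample(c(100, 1000), 1),
                    density_kb_per_snp = sample(c(20, 50, 1000), 1))
    cg <- make_calls(gt, pos)
    got <- suppressWarnings(call_roh_window(cg, p))
    want <- oracle_window_scan(gt, pos, p)
    expect_equal(nrow(got), nrow(want), info = sprintf("case %d", case))
    if (nrow(want)) {
      expect_equal(got$start, want$start, info = sprintf("case %d", case))
      expect_equal(got$end, want$end, info = sprintf("case %d", case))
      expect_equal(got$n_snps, want$n_snps, info = sprintf("case %d", case))
    }
  }
})

test_that("HMM caller finds homozygous tracts and validates parameters", {
  pos <- (1:1000) * 1000L
  cg <- make_calls(rep(0L, 1000), pos)
  segs <- call_roh_hmm(cg, hmm_params())
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$caller, "hmm")
  expect_equal(segs$n_snps, 1000L)
  expect_error(hmm_params(p_het_in_roh = 0.1, p_het_outside = 0.1),
               "smaller")
})

test_that("Viterbi path is optimal against exhaustive enumeration", {
  set.seed(11)
  h <- hmm_params(p_het_in_roh = 0.02, p_het_outside = 0.31,
                  mean_roh_len = 5e5, mean_non_roh_len = 7e5)
  for (case in 1:60) {
    m <- sample(4:12, 1)
    pos <- sort(sample.int(2e6, m))
    gt <- random_gt(m, p_het = 0.4, p_miss = 0.1)
    cg <- make_calls(gt, pos)
    segs <- call_roh_hmm(cg, h)
    st <- path_from_segments(segs, pos)
    sc <- oracle_hmm_score(st, gt, pos, h)
    best <- oracle_hmm_best(gt, pos, h)
    expect_lt(abs(sc - best$score), 1e-9)
  }
})

test_that("gap_merge follows the gap/flank rule and is idempotent", {
  # 5 Mb + 3.77 Mb with a 300 kb gap: flank >= 4 Mb -> one 9.07 Mb segment
  segs <- make_segs(start = c(0, 5.3e6), end = c(5e6, 9.07e6),
                    n_snps = c(5000L, 3770L))
  m <- gap_merge(segs)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 0)
  expect_equal(m$end, 9.07e6)
  expect_equal(m$n_snps, 8770L)
  # 3 Mb + 3 Mb with a 300 kb gap: both flanks < 4 Mb -> unmerged
  segs2 <- make_segs(start = c(0, 3.3e6), end = c(3e6, 6.3e6))
  expect_equal(nrow(gap_merge(segs2)), 2L)
  # gap larger than 500 kb: unmerged even with long flanks
  segs3 <- make_segs(start = c(0, 5.6e6), end = c(5e6, 11e6))
  expect_equal(nrow(gap_merge(segs3)), 2L)
  # single segment unchanged; idempotence; total length non-decreasing
  one <- make_segs(1e6, 2e6)
  expect_equal(gap_merge(one), one)
  expect_equal(gap_merge(m), m)
  expect_gte(sum(m$end - m$start), sum(segs$end - segs$start))
  # chained merging reaches a fixpoint across several fragments
  segs4 <- make_segs(start = c(0, 4.2e6, 8.4e6), end = c(4e6, 8.2e6, 9e6))
  m4 <- gap_merge(segs4)
  expect_equal(nrow(m4), 1L)
  expect_identical(gap_merge(m4), m4)
  # overlapping inputs are rejected
  bad <- make_segs(start = c(0, 1e6), end = c(2e6, 3e6))
  expect_error(gap_merge(bad), "overlap")
  # different contigs/individuals never merge
  two <- make_segs(start = c(0, 5.1e6), end = c(5e6, 10e6),
                   contig = c("chr1", "chr2"))
  expect_equal(nrow(gap_merge(two)), 2L)
})

test_that("filter_min_length applies a strict span threshold", {
  segs <- make_segs(start = c(0, 0, 0), end = c(499000, 501000, 500000))
  out <- filter_min_length(segs, 500)
  expect_equal(nrow(out), 1L)
  expect_equal(out$end, 501000)
})

test_that("pipeline segments never overlap within an individual and contig", {
  cfg <- tiny_cfg(seed = 23L, targets = c(0.2, 0.45))
  ref <- make_reference(cfg)
  pop <- plant_population(ref, cfg)
  for (id in vs_samples(pop$variants)) {
    segs <- call_pipeline(calls_from_truth(pop$variants, id))
    expect_gt(nrow(segs), 0L)
    if (nrow(segs) > 1) {
      s <- segs[order(segs$contig, segs$start), ]
      same <- s$contig[-1] == s$contig[-nrow(s)]
      expect_true(all(s$start[-1][same] >= s$end[-nrow(s)][same]))
    }
  }
})
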