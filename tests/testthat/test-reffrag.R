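test_that("insert_gaps replaces bases in place and preserves coordinates", {
  cfg <- sim_config(n_contigs = 1L, contig_len = 1e6, seed = 31L)
  ref <- make_reference(cfg)
  # zero insertions: unchanged, empty gap map
  z <- insert_gaps(ref, 0L, seed = 1L)
  expect_identical(z$ref$contigs, ref$contigs)
  expect_equal(nrow(z$gapmap), 0L)
  # one insertion of 300 Ns: exactly 300 N bases, two contig segments
  one <- insert_gaps(ref, 1L, seed = 4L)
  r <- charToRaw(one$ref$contigs[[1]])
  expect_equal(sum(r == charToRaw("N")), 300L)
  st <- contig_stats(one$ref)
  expect_equal(st$n_contigs, 2L)
  expect_equal(st$total_non_n, 1e6 - 300)
  # every non-gap position carries the original base
  gm <- one$gapmap
  keep <- setdiff(seq_len(1e6), (gm$start[1] + 1):gm$end[1])
  expect_identical(r[keep], charToRaw(ref$contigs[[1]])[keep])
  # k insertions: <= k+1 segments, non-N length reduced by <= 300k
  k <- 25L
  many <- insert_gaps(ref, k, seed = 9L)
  stk <- contig_stats(many$ref)
  expect_lte(stk$n_contigs, k + 1L)
  expect_gte(stk$total_non_n, 1e6 - 300 * k)
  expect_equal(stk$total_non_n, 1e6 - interval_total_len(many$gapmap))
  # capacity guard
  expect_error(insert_gaps(ref, 1e5, gap_len = 300, seed = 1L), "capacity")
})

test_that("contig_stats implements the N50 definition", {
  # single contig: N50 = max = length
  ref1 <- roh_reference(c(chr1 = strrep("A", 20000)))
  s1 <- contig_stats(ref1)
  expect_equal(s1$contig_n50, 20000)
  expect_equal(s1$max_contig, 20000)
  # forced example: segments {40,30,20,10} -> N50 30, max 40
  st <- contig_stats(list(clens = c(chr1 = 103),
                          gapmap = data.frame(contig = "chr1",
                                              start = c(40, 71, 92),
                                              end = c(41, 72, 93))))
  expect_equal(st$contig_n50, 30)
  expect_equal(st$max_contig, 40)
  expect_equal(st$n_contigs, 4L)
  # all-N reference errors
  expect_error(contig_stats(roh_reference(c(chr1 = "NNNN"))), "non-N")
})

test_that("contig_stats equals the sort-and-scan oracle on random segmentations", {
  set.seed(19)
  for (case in 1:200) {
    lens <- sample.int(5000, sample(1:40, 1), replace = TRUE)
    # build a gap map realising exactly these segment lengths
    gap <- 10
    starts <- cumsum(c(0, head(lens, -1) + gap))
    clen <- sum(lens) + gap * (length(lens) - 1)
    gm <- if (length(lens) > 1) {
      data.frame(contig = "chr1", start = starts[-1] - gap, end = starts[-1])
    } else empty_gm <- data.frame(contig = character(), start = numeric(),
                                  end = numeric())
    st <- contig_stats(list(clens = c(chr1 = clen), gapmap = gm))
    expect_equal(st$contig_n50, oracle_n50(lens))
    expect_equal(st$max_contig, max(lens))
  }
})

test_that("fragment_to_ladder hits descending targets within a factor 2", {
  cfg <- sim_config(n_contigs = 2L, contig_len = 5e6, seed = 37L)
  ref <- make_reference(cfg)
  # target = contig length: the unfragmented reference
  top <- fragment_to_ladder(ref, 5e6, seed = 1L)
  expect_equal(nrow(top[[1]]$gapmap), 0L)
  expect_equal(top[[1]]$achieved_n50, 5e6)
  targets <- c(2e6, 6e5, 1e5)
  lad <- fragment_to_ladder(ref, targets, seed = 1L)
  ach <- vapply(lad, `[[`, numeric(1), "achieved_n50")
  expect_true(all(diff(ach) <= 0))
  expect_true(all(ach <= 2 * targets & ach >= targets / 2))
  # achieved stats agree with recomputation from the gap map
  st <- contig_stats(list(clens = ref_lengths(ref), gapmap = lad[[2]]$gapmap))
  expect_equal(st$contig_n50, lad[[2]]$achieved_n50)
  # materialised sequence agrees with the gap map
  lad2 <- fragment_to_ladder(ref, 1e6, seed = 2L, keep_sequences = TRUE)
  st2 <- contig_stats(lad2[[1]]$ref)
  expect_equal(st2$contig_n50, lad2[[1]]$achieved_n50)
  expect_error(fragment_to_ladder(ref, c(1e5, 2e6), seed = 1L), "descending")
  expect_error(fragment_to_ladder(ref, 500, seed = 1L), "resolution")
})

test_that("apply_fragmentation omits in-gap sites and corrupts gap edges", {
  cg <- make_calls(c(0L, 1L, 2L, 0L, 1L),
                   c(1000L, 5000L, 10500L, 30000L, 200000L))
  # empty gap map: untouched
  expect_identical(apply_fragmentation(cg, empty_gm <- data.frame(
    contig = character(), start = numeric(), end = numeric())), cg)
  gm <- data.frame(contig = "chr1", start = 10000, end = 10300)
  # site at 10,500 is inside? no: gap is [10000,10300); 10500 is 200 bp past
  # the boundary -> edge zone; site 10,250 would be in-gap
  cg2 <- make_calls(c(0L, 1L, 2L), c(10250L, 10500L, 10290L))
  out <- apply_fragmentation(cg2, gm, frag_effect(edge_window = 5000,
                                                  edge_err = 0), seed = 1L)
  expect_true(is.na(out$gt[out$sites$pos == 10250]))
  expect_true(is.na(out$gt[out$sites$pos == 10290]))
  expect_equal(out$gt[out$sites$pos == 10500], 1L)
  # edge_err = 1: every near-gap call flips hom<->het
  out2 <- apply_fragmentation(cg, gm, frag_effect(edge_window = 5000,
                                                  edge_err = 1), seed = 1L)
  expect_true(out2$gt[cg$sites$pos == 5000] %in% c(0L, 2L))  # het -> hom
  expect_equal(out2$gt[cg$sites$pos == 10500], 1L)           # hom -> het
  # sites beyond the edge window are untouched
  expect_equal(out2$gt[cg$sites$pos == 1000], 0L)
  expect_equal(out2$gt[cg$sites$pos == 30000], 0L)
  expect_equal(out2$gt[cg$sites$pos == 200000], 1L)
})

test_that("diverge_reference composes substitution noise with breakpoints", {
  cfg <- sim_config(n_contigs = 1L, contig_len = 1e5, seed = 41L)
  ref <- make_reference(cfg)
  # identity when both effects are off
  id <- diverge_reference(ref, 0, 0L, seed = 1L)
  expect_identical(id$ref$contigs, ref$contigs)
  expect_equal(nrow(id$effect$implied_gapmap), 0L)
  cg <- make_calls(rep(0L, 50), seq(1000L, 99000L, length.out = 50))
  expect_identical(apply_divergence(cg, id$effect), cg)
  # k breakpoints -> k implied gap entries, genome length conserved
  dv <- diverge_reference(ref, 0.01, 5L, seed = 2L)
  expect_equal(nrow(dv$effect$implied_gapmap), 5L)
  expect_equal(ref_total_len(dv$ref), 1e5)
  expect_error(diverge_reference(ref, 0.2, 0L), "subst_rate")
})

test_that("rearrangement breakpoints fragment long ROH like assembly gaps", {
  mix <- data.frame(min_mb = c(5, 10), max_mb = c(10, 22),
                    weight = c(0.5, 0.5))
  cfg <- sim_config(n_contigs = 2L, contig_len = 25e6, seed = 4202L,
                    target_f_roh_levels = seq(0.30, 0.55, length.out = 8),
                    roh_length_mix = mix, min_roh_len = 5e6)
  ref <- make_reference(cfg)
  pop <- plant_population(ref, cfg)
  counts <- sapply(c(0L, 40L, 120L), function(k) {
    big <- 0; small <- 0
    for (s in 1:3) {
      dv <- diverge_reference(ref, 0, k, seed = s)
      for (id in vs_samples(pop$variants)) {
        cg <- apply_divergence(calls_from_truth(pop$variants, id),
                               dv$effect, seed = s + 100L)
        segs <- call_pipeline(cg)
        big <- big + sum(segs$end - segs$start > 5e6)
        small <- small + sum(segs$end - segs$start <= 5e6)
      }
    }
    c(big = big, small = small)
  })
  # more breakpoints: fewer long segments, more short fragments
  expect_true(all(diff(counts["big", ]) <= 0))
  expect_gt(counts["big", 1], counts["big", 3])
  expect_true(all(diff(counts["small", ]) >= 0))
  expect_gt(counts["small", 3], counts["small", 1])
})
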