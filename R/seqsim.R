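#' Simulate error-free paired-end reads from a haplotype pair
#'
#' wgsim-style simulation: fragments are drawn uniformly along each
#' haplotype with normally distributed fragment lengths, and the two mates
#' are the fragment's ends. Reads are represented by their true origin
#' (haplotype, contig, fragment start/length) rather than materialised
#' sequences; [write_fastq()] materialises them on demand. The number of
#' pairs per haplotype is `round(depth * len / (2 * 2 * read_len))` so that
#' the pooled (diploid) depth across both haplotypes equals `depth`.
#'
#' @param hp a `roh_haplotypes`.
#' @param depth target diploid fold-coverage (> 0).
#' @param read_len read length in bases (30, 50, 75, 100 or 150 in the
#'   benchmark; any value `<= frag_mean` is accepted).
#' @param frag_mean,frag_sd fragment length mean and standard deviation
#'   (wgsim defaults 500 and 50).
#' @param err_rate per-base sequencing error probability (default 0,
#'   matching error-free simulation; applied when sequences are
#'   materialised and folded into the pileup miscall probability).
#' @param seed integer seed.
#' @return An object of class `roh_reads`.
#' @export
simulate_reads <- function(hp, depth, read_len = 100L, frag_mean = 500,
                           frag_sd = 50, err_rate = 0, seed = 1L) {
  if (depth <= 0) stop_config("depth must be > 0")
  if (err_rate < 0 || err_rate >= 1) stop_config("err_rate must be in [0,1)")
  if (read_len > frag_mean)
    stop_config("read_len (%d) must not exceed frag_mean (%g)", read_len, frag_mean)
  frags <- with_seed(child_seed(seed, "reads", hp$individual, read_len), {
    out <- list()
    for (ct in names(hp$hapA)) {
      clen <- nchar(hp$hapA[[ct]])
      if (clen < frag_mean) {
        warning(sprintf("contig %s shorter than frag_mean; skipped", ct))
        next
      }
      per_hap <- list()
      for (h in c("A", "B")) {
        n <- round(depth * clen / (4 * read_len))
        fl <- pmin(clen, pmax(read_len, round(rnorm(n, frag_mean, frag_sd))))
        st <- floor(runif(n, 1, clen - fl + 2))   # 1-based fragment start
        per_hap[[h]] <- list(start = as.integer(st), len = as.integer(fl))
      }
      out[[ct]] <- per_hap
    }
    out
  })
  structure(list(individual = hp$individual, read_len = as.integer(read_len),
                 frag_mean = frag_mean, frag_sd = frag_sd,
                 err_rate = err_rate, depth = depth, frags = frags),
            class = "roh_reads")
}

#' @export
print.roh_reads <- function(x, ...) {
  cat(sprintf("<roh_reads> %s: %s pair(s), %d bp reads, nominal depth %.3gx\n",
              x$individual, format(n_pairs(x), big.mark = ","),
              x$read_len, x$depth))
  invisible(x)
}

#' Number of read pairs in a read set
#' @param reads a `roh_reads`.
#' @return Total read-pair count.
#' @export
n_pairs <- function(reads) {
  sum(vapply(reads$frags, function(ct)
    length(ct$A$start) + length(ct$B$start), numeric(1)))
}

#' Randomly thin a read set to a fraction of its pairs
#'
#' Bernoulli thinning of read pairs, emulating random selection of raw
#' sequencing data to build lower-depth groups from one high-depth run.
#'
#' @param reads a `roh_reads`.
#' @param fraction keep probability in (0, 1].
#' @param seed integer seed.
#' @return A `roh_reads` with the surviving pairs and rescaled nominal depth.
#' @export
subsample_depth <- function(reads, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1)
    stop_config("fraction must be in (0, 1]")
  if (fraction == 1) return(reads)
  out <- reads
  with_seed(child_seed(seed, "subs", reads$individual, round(1e9 * fraction)), {
    for (ct in names(reads$frags)) {
      for (h in c("A", "B")) {
        fr <- reads$frags[[ct]][[h]]
        keep <- runif(length(fr$start)) < fraction
        out$frags[[ct]][[h]] <- list(start = fr$start[keep], len = fr$len[keep])
      }
    }
  })
  out$depth <- reads$depth * fraction
  out
}

#' Pileup calling configuration
#'
#' Threshold-based genotype model standing in for a full mapping-plus-
#' likelihood pipeline: a site is missing below `min_depth` reads; an allele
#' counts as observed once it is seen on `min_allele_reads` reads; a site
#' with both alleles observed is het, otherwise a homozygote of the observed
#' allele. Het-to-hom "allele dropout" then arises naturally at low depth.
#'
#' @param min_depth minimum reads at a site for a non-missing call. The
#'   default of 1 mirrors likelihood-based callers, which emit a genotype
#'   from a single read at low coverage; raising it trades het-to-hom
#'   dropout for missingness.
#' @param min_allele_reads reads needed to count an allele as observed.
#' @param base_err per-base miscall probability applied at pileup.
#' @return An object of class `roh_call_config`.
#' @export
call_config <- function(min_depth = 1L, min_allele_reads = 1L, base_err = 0) {
  if (min_depth < 1L) stop_config("min_depth must be >= 1")
  if (base_err < 0 || base_err >= 1) stop_config("base_err must be in [0,1)")
  structure(list(min_depth = as.integer(min_depth),
                 min_allele_reads = as.integer(min_allele_reads),
                 base_err = base_err),
            class = "roh_call_config")
}

# count reads (sorted 1-based starts, fixed read length) overlapping each pos
count_overlaps_sorted <- function(starts_sorted, pos, read_len) {
  findInterval(pos, starts_sorted) -
    findInterval(pos - read_len, starts_sorted)
}

#' Origin-aware pileup genotype caller
#'
#' Counts, per assayable site, the reads overlapping it from each haplotype;
#' each read reports its haplotype's base (flipped to the other allele with
#' the combined miscall probability from `err_rate` and `base_err`), and the
#' genotype is called by the threshold rule of [call_config()]. Because
#' reads carry their true origin there is no alignment stage.
#'
#' @param reads a `roh_reads` for one individual.
#' @param sites data.frame with columns `contig`, `pos`, `ref`, `alt`
#'   (typically `vs$sites` of the population variant set).
#' @param hp the `roh_haplotypes` the reads were simulated from.
#' @param cc a [call_config()].
#' @param seed integer seed (used when the miscall probability is > 0).
#' @return An object of class `roh_calls`: list with `sites`
#'   (`contig`, `pos`), `gt` (0/1/2/NA) and `dp` (site depth).
#' @export
pileup_call <- function(reads, sites, hp, cc = call_config(), seed = 1L) {
  rl <- reads$read_len
  p_err <- 1 - (1 - reads$err_rate) * (1 - cc$base_err)
  gt <- rep(NA_integer_, nrow(sites))
  dp <- integer(nrow(sites))
  with_seed(child_seed(seed, "pileup", reads$individual), {
    for (ct in unique(sites$contig)) {
      sel <- which(sites$contig == ct)
      pos <- sites$pos[sel]
      clen <- nchar(hp$hapA[[ct]])
      if (any(pos < 1L | pos > clen))
        stop_config("site outside contig bounds on %s", ct)
      fr <- reads$frags[[ct]]
      if (is.null(fr)) { gt[sel] <- NA_integer_; next }
      nref <- integer(length(pos))
      nalt <- integer(length(pos))
      for (h in c("A", "B")) {
        f <- fr[[h]]
        starts <- sort(c(f$start, f$start + f$len - rl))
        cnt <- count_overlaps_sorted(starts, pos, rl)
        hb <- ref_base_at(hp[[paste0("hap", h)]][[ct]], pos)
        is_alt <- hb == sites$alt[sel]
        bad <- !is_alt & hb != sites$ref[sel]
        if (any(bad))
          stop_config("haplotype base at %s:%d is neither ref nor alt",
                      ct, pos[which(bad)[1]])
        nref <- nref + ifelse(is_alt, 0L, cnt)
        nalt <- nalt + ifelse(is_alt, cnt, 0L)
      }
      if (p_err > 0) {
        flip_r <- rbinom(length(pos), nref, p_err)
        flip_a <- rbinom(length(pos), nalt, p_err)
        nref <- nref - flip_r + flip_a
        nalt <- nalt - flip_a + flip_r
      }
      d <- nref + nalt
      g <- rep(NA_integer_, length(pos))
      called <- d >= cc$min_depth
      both <- called & nref >= cc$min_allele_reads & nalt >= cc$min_allele_reads
      g[both] <- 1L
      homr <- called & !both & nref > nalt
      homa <- called & !both & nalt > nref
      g[homr] <- 0L
      g[homa] <- 2L
      # called, not het, and tied counts below the allele threshold: ambiguous
      g[called & !both & nref == nalt & nref > 0L] <- NA_integer_
      g[called & nref == 0L & nalt == 0L] <- NA_integer_
      gt[sel] <- g
      dp[sel] <- d
    }
  })
  structure(list(individual = reads$individual,
                 sites = sites[, c("contig", "pos")],
                 gt = gt, dp = dp, call_config = cc),
            class = "roh_calls")
}

#' @export
print.roh_calls <- function(x, ...) {
  cat(sprintf("<roh_calls> %s: %d site(s), %.1f%% missing, mean depth %.2f\n",
              x$individual, length(x$gt), 100 * mean(is.na(x$gt)),
              mean(x$dp)))
  invisible(x)
}

#' Perfect calls taken directly from truth genotypes
#'
#' Convenience constructor: the error-free, infinite-depth limit of
#' [pileup_call()] for one individual of a variant set.
#'
#' @param vs a `roh_variants`.
#' @param individual sample name.
#' @return A `roh_calls`.
#' @export
calls_from_truth <- function(vs, individual) {
  if (!individual %in% vs_samples(vs))
    stop_config("individual '%s' not present in variant set", individual)
  structure(list(individual = individual,
                 sites = vs$sites[, c("contig", "pos")],
                 gt = vs$geno[, individual],
                 dp = rep(NA_integer_, nrow(vs$sites)),
                 call_config = NULL),
            class = "roh_calls")
}

#' Assemble per-individual calls into a multi-sample variant set
#'
#' @param calls_list list of `roh_calls` over the same site table.
#' @param sites the shared site data.frame (`contig`, `pos`, `ref`, `alt`).
#' @return A `roh_variants` whose genotype matrix may contain NA (missing).
#' @export
calls_to_variants <- function(calls_list, sites) {
  geno <- vapply(calls_list, function(x) {
    if (length(x$gt) != nrow(sites))
      stop_config("call set has a different site universe")
    x$gt
  }, integer(nrow(sites)))
  colnames(geno) <- vapply(calls_list, `[[`, character(1), "individual")
  roh_variants(sites, geno)
}

#' SNP error ratio of a call set against truth
#'
#' The number of erroneously called SNPs over the number of truth variant
#' sites of the individual, with missing sites reported separately as a
#' missingness rate.
#'
#' @param called a `roh_calls`.
#' @param vs the truth `roh_variants` (same site universe).
#' @param individual sample name in `vs`.
#' @return List with `error_ratio`, `missing_rate` and `n_truth_sites`.
#' @export
snp_error_ratio <- function(called, vs, individual) {
  if (!individual %in% vs_samples(vs))
    stop_config("individual '%s' not present in variant set", individual)
  if (nrow(called$sites) == nrow(vs$sites) &&
      identical(called$sites$pos, vs$sites$pos) &&
      identical(called$sites$contig, vs$sites$contig)) {
    idx <- seq_len(nrow(vs$sites))   # same site universe: avoid keying
  } else {
    key_t <- paste(vs$sites$contig, vs$sites$pos)
    key_c <- paste(called$sites$contig, called$sites$pos)
    idx <- match(key_t, key_c)
    if (anyNA(idx)) stop_config("call set does not cover the truth sites")
  }
  tgt <- vs$geno[, individual]
  cgt <- called$gt[idx]
  n_truth <- sum(tgt > 0L, na.rm = TRUE)
  if (n_truth == 0L) stop_config("individual has no truth variant sites")
  wrong <- !is.na(cgt) & cgt != tgt
  miss <- is.na(cgt) & tgt > 0L
  list(error_ratio = sum(wrong) / n_truth,
       missing_rate = sum(miss) / n_truth,
       n_truth_sites = n_truth)
}

#' Realised mean depth of a read set
#' @param reads a `roh_reads`.
#' @param hp the source `roh_haplotypes` (for contig lengths).
#' @return Mean per-base fold-coverage implied by the read count.
#' @export
realized_depth <- function(reads, hp) {
  n_reads <- 2 * n_pairs(reads)
  n_reads * reads$read_len / sum(nchar(hp$hapA))
}

#' Materialise a read set as paired FASTQ files
#'
#' Writes `<prefix>_1.fq` and `<prefix>_2.fq` (Phred+33, constant quality
#' 'I'); mate 2 is reverse-complemented. Read names encode the true origin
#' as `individual|haplotype|contig|start|i`. Per-base errors are injected at
#' `err_rate` by substituting a random different base.
#'
#' @param reads a `roh_reads`.
#' @param hp the source `roh_haplotypes`.
#' @param prefix output path prefix.
#' @param seed integer seed for error injection.
#' @return Character vector of the two paths, invisibly.
#' @export
write_fastq <- function(reads, hp, prefix, seed = 1L) {
  rl <- reads$read_len
  ids <- character(0); m1 <- character(0); m2 <- character(0)
  for (ct in names(reads$frags)) {
    for (h in c("A", "B")) {
      f <- reads$frags[[ct]][[h]]
      if (!length(f$start)) next
      hseq <- hp[[paste0("hap", h)]][[ct]]
      s1 <- substring(hseq, f$start, f$start + rl - 1L)
      e2 <- f$start + f$len - 1L
      s2 <- substring(hseq, e2 - rl + 1L, e2)
      s2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s2)))
      ids <- c(ids, sprintf("%s|%s|%s|%d|%d", reads$individual, h, ct,
                            f$start, seq_along(f$start)))
      m1 <- c(m1, s1); m2 <- c(m2, s2)
    }
  }
  if (reads$err_rate > 0 && length(m1)) {
    inject <- function(seqs, key) with_seed(child_seed(seed, key), {
      vapply(seqs, function(s) {
        hit <- which(runif(nchar(s)) < reads$err_rate)
        if (length(hit)) {
          b <- c("A", "C", "G", "T")
          cur <- ref_base_at(s, hit)
          repl <- vapply(cur, function(x) sample(setdiff(b, x), 1L), character(1))
          s <- seq_replace_at(s, hit, repl)
        }
        s
      }, character(1), USE.NAMES = FALSE)
    })
    m1 <- inject(m1, "fq1"); m2 <- inject(m2, "fq2")
  }
  qual <- strrep("I", rl)
  p1 <- paste0(prefix, "_1.fq"); p2 <- paste0(prefix, "_2.fq")
  writeLines(rbind(paste0("@", ids, "/1"), m1, "+", qual), p1)
  writeLines(rbind(paste0("@", ids, "/2"), m2, "+", qual), p2)
  invisible(c(p1, p2))
}
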