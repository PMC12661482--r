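#' PLINK-style ROH detection parameters
#'
#' The seven knobs of the two-step PLINK procedure plus the window
#' allowances PLINK fixes by default. Step 1 (`--indep-pairwise n1 n2 n3`)
#' prunes SNP pairs whose dosage r-squared exceeds `prune_r2` within a
#' sliding window; step 2 (`--homozyg`) scans the genome with a window of
#' `window_snps` SNPs and reports regions longer than `min_kb` kb with at
#' least `min_snps` SNPs as ROH.
#'
#' @param prune_window LD-pruning window size (`n1`); interpreted in SNPs or
#'   kb according to `prune_window_unit` (the published command line
#'   `--indep-pairwise 50 1 0.8` is a SNP-count window in PLINK, so "snp" is
#'   the default unit).
#' @param prune_window_unit "snp" or "kb".
#' @param prune_step window advance in SNPs (`n2`).
#' @param prune_r2 r-squared threshold (`n3`); `NA` disables pruning.
#' @param window_snps sliding-window size in SNPs (`n4`).
#' @param density_kb_per_snp maximum mean kb per SNP inside a reported
#'   segment (`n5`, PLINK `--homozyg-density` semantics).
#' @param min_kb minimum segment span in kb (`n6`).
#' @param min_snps minimum SNP count in a segment (`n7`).
#' @param window_het_allow maximum het calls for a window to count as
#'   homozygous (PLINK `--homozyg-window-het`).
#' @param window_missing_allow maximum missing calls per window
#'   (PLINK `--homozyg-window-missing`).
#' @param window_hit_threshold minimum fraction of homozygous windows
#'   containing a site for the site to pass
#'   (PLINK `--homozyg-window-threshold`).
#' @param max_internal_gap_kb split candidate segments at inter-site gaps
#'   larger than this (PLINK `--homozyg-gap`).
#' @return An object of class `roh_params`.
#' @export
roh_params <- function(prune_window = 50L, prune_window_unit = c("snp", "kb"),
                       prune_step = 1L, prune_r2 = NA_real_,
                       window_snps = 50L, density_kb_per_snp = 50,
                       min_kb = 500, min_snps = 100L,
                       window_het_allow = 1L, window_missing_allow = 5L,
                       window_hit_threshold = 0.05,
                       max_internal_gap_kb = 1000) {
  prune_window_unit <- match.arg(prune_window_unit)
  if (window_snps < 1L) stop_config("window_snps must be >= 1")
  if (!is.na(prune_r2) && (prune_r2 < 0 || prune_r2 > 1))
    stop_config("prune_r2 must be in [0,1]")
  if (window_hit_threshold <= 0 || window_hit_threshold > 1)
    stop_config("window_hit_threshold must be in (0,1]")
  if (min_kb <= 0) stop_config("min_kb must be > 0")
  structure(list(prune_window = as.integer(prune_window),
                 prune_window_unit = prune_window_unit,
                 prune_step = as.integer(prune_step),
                 prune_r2 = prune_r2,
                 window_snps = as.integer(window_snps),
                 density_kb_per_snp = density_kb_per_snp,
                 min_kb = min_kb, min_snps = as.integer(min_snps),
                 window_het_allow = as.integer(window_het_allow),
                 window_missing_allow = as.integer(window_missing_allow),
                 window_hit_threshold = window_hit_threshold,
                 max_internal_gap_kb = max_internal_gap_kb),
            class = "roh_params")
}

#' @export
print.roh_params <- function(x, ...) {
  cat(sprintf(paste0("<roh_params> prune: %s; window %d SNPs (het<=%d, ",
                     "miss<=%d, hit>=%.2f), density %g kb/SNP, gap %g kb, ",
                     "min %g kb / %d SNPs\n"),
              if (is.na(x$prune_r2)) "off" else
                sprintf("%d %s / step %d / r2 %.2f", x$prune_window,
                        x$prune_window_unit, x$prune_step, x$prune_r2),
              x$window_snps, x$window_het_allow, x$window_missing_allow,
              x$window_hit_threshold, x$density_kb_per_snp,
              x$max_internal_gap_kb, x$min_kb, x$min_snps))
  invisible(x)
}

# segments constructor; 0-based half-open coordinates in bases
roh_segments <- function(iid = character(), contig = character(),
                         start = numeric(), end = numeric(),
                         n_snps = integer(), caller = character()) {
  df <- data.frame(iid = iid, contig = contig, start = start, end = end,
                   n_snps = n_snps, caller = caller, stringsAsFactors = FALSE)
  class(df) <- c("roh_segments", "data.frame")
  df
}

segment_span <- function(segs) segs$end - segs$start

#' LD pruning of a population genotype matrix
#'
#' Greedy windowed pruning: within each window, any pair of kept sites
#' whose allele-dosage squared correlation (pairwise-complete over
#' individuals) exceeds `prune_r2` has its later site removed. Returns the
#' surviving site indices in order.
#'
#' @param vs a `roh_variants` (needs at least two individuals; with one,
#'   r-squared is undefined and pruning is a warning no-op).
#' @param params a [roh_params()] with a non-NA `prune_r2`.
#' @return Integer vector of kept site indices into `vs$sites`.
#' @export
ld_prune <- function(vs, params = roh_params(prune_r2 = 0.8)) {
  m <- nrow(vs$sites)
  if (is.na(params$prune_r2)) return(seq_len(m))
  if (ncol(vs$geno) < 2L) {
    warning("ld_prune: fewer than 2 individuals; pruning skipped")
    return(seq_len(m))
  }
  kept <- logical(m)
  for (ct in unique(vs$sites$contig)) {
    sel <- which(vs$sites$contig == ct)
    kept[sel] <- ld_prune_cpp(vs$geno[sel, , drop = FALSE],
                              as.numeric(vs$sites$pos[sel]),
                              params$prune_window,
                              params$prune_window_unit == "kb",
                              params$prune_step, params$prune_r2)
  }
  which(kept)
}

#' Sliding-window homozygosity scan (PLINK-style ROH caller)
#'
#' For every contiguous window of `window_snps` sites, the window is
#' homozygous iff its het count and missing count are within the window
#' allowances; a site passes iff the fraction of windows containing it that
#' are homozygous reaches `window_hit_threshold`; maximal runs of passing
#' sites, trimmed to homozygous non-missing end calls and split at
#' inter-site gaps above `max_internal_gap_kb`, are reported when they span
#' at least `min_kb` kb, contain at least `min_snps` sites and keep a mean
#' density of at most `density_kb_per_snp` kb per SNP.
#'
#' @param cg a `roh_calls` (sorted sites; 0/1/2/NA genotypes).
#' @param params a [roh_params()].
#' @return A `roh_segments` data.frame (`iid`, `contig`, `start`, `end`,
#'   `n_snps`, `caller`), 0-based half-open base coordinates.
#' @export
call_roh_window <- function(cg, params = roh_params()) {
  W <- params$window_snps
  out <- list()
  for (ct in unique(cg$sites$contig)) {
    sel <- which(cg$sites$contig == ct)
    g <- cg$gt[sel]
    pos <- cg$sites$pos[sel]
    m <- length(g)
    if (m < W) {
      warning(sprintf("contig %s has %d < %d sites; skipped", ct, m, W))
      next
    }
    nw <- m - W + 1L
    het_c <- cumsum(c(0L, !is.na(g) & g == 1L))
    mis_c <- cumsum(c(0L, is.na(g)))
    hom_w <- (het_c[(W + 1):(m + 1)] - het_c[1:nw]) <= params$window_het_allow &
             (mis_c[(W + 1):(m + 1)] - mis_c[1:nw]) <= params$window_missing_allow
    S <- cumsum(c(0L, hom_w))
    j <- seq_len(m)
    lo <- pmax(1L, j - W + 1L)
    hi <- pmin(j, nw)
    hits <- S[hi + 1L] - S[lo]
    pass <- hits / (hi - lo + 1L) >= params$window_hit_threshold
    r <- rle(pass)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hom_site <- !is.na(g) & g != 1L
    for (k in which(r$values)) {
      i1 <- starts[k]; i2 <- ends[k]
      hh <- which(hom_site[i1:i2])
      if (!length(hh)) next
      i1t <- i1 + hh[1] - 1L
      i2t <- i1 + hh[length(hh)] - 1L
      # split at large internal gaps
      idx <- i1t:i2t
      if (length(idx) > 1L) {
        brk <- which(diff(pos[idx]) > params$max_internal_gap_kb * 1000)
      } else brk <- integer(0)
      piece_start <- c(1L, brk + 1L)
      piece_end <- c(brk, length(idx))
      for (p in seq_along(piece_start)) {
        ii <- idx[piece_start[p]:piece_end[p]]
        span <- pos[ii[length(ii)]] - pos[ii[1]] + 1L
        nsnp <- length(ii)
        if (span >= params$min_kb * 1000 && nsnp >= params$min_snps &&
            span / 1000 / nsnp <= params$density_kb_per_snp) {
          out[[length(out) + 1L]] <- data.frame(
            iid = cg$individual %||% NA_character_, contig = ct,
            start = pos[ii[1]] - 1, end = as.numeric(pos[ii[length(ii)]]),
            n_snps = nsnp, caller = "window", stringsAsFactors = FALSE)
        }
      }
    }
  }
  df <- if (length(out)) do.call(rbind, out) else
    roh_segments()
  class(df) <- c("roh_segments", "data.frame")
  rownames(df) <- NULL
  df
}

#' Parameters of the two-state HMM ROH caller
#'
#' @param p_het_in_roh per-site het emission probability inside ROH
#'   (genotyping error floor).
#' @param p_het_outside per-site het emission probability outside ROH; must
#'   exceed `p_het_in_roh`.
#' @param mean_roh_len,mean_non_roh_len mean state tract lengths in bases;
#'   the probability of leaving a state across an inter-site distance d is
#'   `1 - exp(-d / mean_state_len)`.
#' @return An object of class `roh_hmm_params`.
#' @export
hmm_params <- function(p_het_in_roh = 0.01, p_het_outside = 0.1,
                       mean_roh_len = 2e6, mean_non_roh_len = 5e6) {
  if (any(c(p_het_in_roh, p_het_outside) <= 0) ||
      any(c(p_het_in_roh, p_het_outside) >= 1))
    stop_config("emission probabilities must be in (0,1)")
  if (p_het_in_roh >= p_het_outside)
    stop_config("p_het_in_roh must be smaller than p_het_outside")
  structure(list(p_het_in_roh = p_het_in_roh, p_het_outside = p_het_outside,
                 mean_roh_len = mean_roh_len,
                 mean_non_roh_len = mean_non_roh_len),
            class = "roh_hmm_params")
}

#' Two-state HMM ROH caller (Viterbi)
#'
#' Simplified likelihood-based alternative to the window scan: hidden
#' states ROH / non-ROH with Bernoulli(het) emissions and distance-dependent
#' transition probabilities; missing sites contribute no emission. Runs of
#' the ROH state along the Viterbi path become segments (unfiltered; apply
#' [gap_merge()] and [filter_min_length()] downstream).
#'
#' @param cg a `roh_calls`.
#' @param h a [hmm_params()].
#' @return A `roh_segments` data.frame with `caller = "hmm"`.
#' @export
call_roh_hmm <- function(cg, h = hmm_params()) {
  out <- list()
  for (ct in unique(cg$sites$contig)) {
    sel <- which(cg$sites$contig == ct)
    g <- cg$gt[sel]
    pos <- cg$sites$pos[sel]
    m <- length(g)
    if (m == 0L) next
    # log emissions: state 1 = ROH, state 2 = non-ROH; missing emits 0
    is_het <- !is.na(g) & g == 1L
    is_obs <- !is.na(g)
    e1 <- ifelse(is_obs, ifelse(is_het, log(h$p_het_in_roh),
                                log1p(-h$p_het_in_roh)), 0)
    e2 <- ifelse(is_obs, ifelse(is_het, log(h$p_het_outside),
                                log1p(-h$p_het_outside)), 0)
    pi1 <- h$mean_roh_len / (h$mean_roh_len + h$mean_non_roh_len)
    v1 <- log(pi1) + e1[1]
    v2 <- log(1 - pi1) + e2[1]
    bt <- matrix(1L, nrow = m, ncol = 2)
    if (m > 1) for (i in 2:m) {
      d <- pos[i] - pos[i - 1]
      stay1 <- exp(-d / h$mean_roh_len)
      stay2 <- exp(-d / h$mean_non_roh_len)
      c11 <- v1 + log(stay1);      c21 <- v2 + log1p(-stay2)
      c12 <- v1 + log1p(-stay1);   c22 <- v2 + log(stay2)
      if (c11 >= c21) { n1 <- c11 + e1[i]; bt[i, 1] <- 1L }
      else            { n1 <- c21 + e1[i]; bt[i, 1] <- 2L }
      if (c22 >= c12) { n2 <- c22 + e2[i]; bt[i, 2] <- 2L }
      else            { n2 <- c12 + e2[i]; bt[i, 2] <- 1L }
      v1 <- n1; v2 <- n2
    }
    path <- integer(m)
    path[m] <- if (v1 >= v2) 1L else 2L
    if (m > 1) for (i in (m - 1):1) path[i] <- bt[i + 1, path[i + 1]]
    r <- rle(path == 1L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      out[[length(out) + 1L]] <- data.frame(
        iid = cg$individual %||% NA_character_, contig = ct,
        start = pos[starts[k]] - 1, end = as.numeric(pos[ends[k]]),
        n_snps = ends[k] - starts[k] + 1L, caller = "hmm",
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(out)) do.call(rbind, out) else roh_segments()
  class(df) <- c("roh_segments", "data.frame")
  rownames(df) <- NULL
  df
}

#' Merge falsely fragmented ROH segments across short gaps
#'
#' Repeatedly merges adjacent segments of the same individual and contig
#' when the gap between them is at most `max_gap_kb` kb AND at least one of
#' the two flanking segments is at least `min_flank_kb` kb long, until no
#' further merge applies. The merged span covers both segments plus the
#' gap; SNP counts are summed.
#'
#' @param segs a `roh_segments` data.frame.
#' @param max_gap_kb maximum bridgeable gap, kb.
#' @param min_flank_kb minimum flanking-segment length for a merge, kb.
#' @return A `roh_segments` data.frame.
#' @export
gap_merge <- function(segs, max_gap_kb = 500, min_flank_kb = 4000) {
  if (nrow(segs) == 0L) return(segs)
  pieces <- split(seq_len(nrow(segs)),
                  paste(segs$iid, segs$contig, sep = "\r"))
  res <- lapply(pieces, function(idx) {
    s <- segs[idx, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (any(s$start[-1] < s$end[-nrow(s)]))
      stop_config("overlapping input segments for %s on %s",
                  s$iid[1], s$contig[1])
    repeat {
      if (nrow(s) < 2L) break
      gap <- s$start[-1] - s$end[-nrow(s)]
      len_l <- (s$end - s$start)[-nrow(s)]
      len_r <- (s$end - s$start)[-1]
      can <- gap <= max_gap_kb * 1000 &
        (len_l >= min_flank_kb * 1000 | len_r >= min_flank_kb * 1000)
      k <- which(can)
      if (!length(k)) break
      k <- k[1]
      s$end[k] <- s$end[k + 1]
      s$n_snps[k] <- s$n_snps[k] + s$n_snps[k + 1]
      s <- s[-(k + 1), , drop = FALSE]
    }
    s
  })
  df <- do.call(rbind, res)
  df <- df[order(df$iid, df$contig, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("roh_segments", "data.frame")
  df
}

#' Drop ROH segments at or below a minimum length
#'
#' Keeps segments whose span exceeds `min_kb` kb, preserving order.
#'
#' @param segs a `roh_segments` data.frame.
#' @param min_kb length threshold, kb.
#' @return The filtered `roh_segments`.
#' @export
filter_min_length <- function(segs, min_kb = 500) {
  out <- segs[segment_span(segs) > min_kb * 1000, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full PLINK-style calling pipeline for one individual
#'
#' Optional LD pruning on the population matrix, window scan on the
#' individual's calls restricted to the kept sites, gap-merging, and the
#' minimum-length filter.
#'
#' @param cg a `roh_calls` for one individual.
#' @param params a [roh_params()]; pruning runs iff `prune_r2` is not NA.
#' @param pop_vs the population `roh_variants` used for LD pruning
#'   (required when pruning is enabled).
#' @param merge apply [gap_merge()] (default TRUE).
#' @param max_gap_kb,min_flank_kb gap-merge settings.
#' @param final_min_kb post-merge length filter, kb.
#' @return A `roh_segments` data.frame.
#' @export
call_pipeline <- function(cg, params = roh_params(), pop_vs = NULL,
                          merge = TRUE, max_gap_kb = 500,
                          min_flank_kb = 4000, final_min_kb = 500) {
  if (!is.na(params$prune_r2)) {
    if (is.null(pop_vs))
      stop_config("LD pruning requested but no population variant set given")
    keep <- ld_prune(pop_vs, params)
    cg <- structure(list(individual = cg$individual,
                         sites = cg$sites[keep, , drop = FALSE],
                         gt = cg$gt[keep], dp = cg$dp[keep],
                         call_config = cg$call_config),
                    class = "roh_calls")
  }
  segs <- suppressWarnings(call_roh_window(cg, params))
  if (merge) segs <- gap_merge(segs, max_gap_kb, min_flank_kb)
  filter_min_length(segs, final_min_kb)
}

#' Write segments as a PLINK `.hom`-style TSV
#'
#' Columns IID, CHR, POS1, POS2, KB, NSNP, CALLER; POS1/POS2 are 1-based
#' inclusive base coordinates.
#'
#' @param segs a `roh_segments`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hom <- function(segs, path) {
  df <- data.frame(IID = segs$iid, CHR = segs$contig,
                   POS1 = segs$start + 1, POS2 = segs$end,
                   KB = (segs$end - segs$start) / 1000,
                   NSNP = segs$n_snps, CALLER = segs$caller)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#'
#' Works for truth intervals, gap maps and ROH segments: any data.frame
#' with `contig`, `start`, `end` columns; a `name` column is taken from
#' `iid` if present.
#'
#' @param iv interval data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(iv, path) {
  df <- data.frame(chrom = iv$contig, start = format(iv$start, scientific = FALSE, trim = TRUE),
                   end = format(iv$end, scientific = FALSE, trim = TRUE))
  if (!is.null(iv$iid)) df$name <- iv$iid
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
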