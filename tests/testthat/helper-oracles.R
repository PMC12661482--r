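# Independent brute-force oracles. These deliberately re-state the rules as
# literal loops, without sharing code with the package implementations.

# exhaustive-window ROH scan: enumerate every window, apply the rules
# (homozygous windows -> per-site hit rate -> runs -> trim -> gap split ->
# span/count/density filters) one by one
oracle_window_scan <- function(gt, pos, p) {
  m <- length(gt)
  W <- p$window_snps
  if (m < W) return(data.frame(start = numeric(0), end = numeric(0),
                               n_snps = integer(0)))
  nw <- m - W + 1L
  hom_w <- logical(nw)
  for (i in seq_len(nw)) {
    w <- gt[i:(i + W - 1L)]
    hom_w[i] <- sum(w == 1L, na.rm = TRUE) <= p$window_het_allow &&
      sum(is.na(w)) <= p$window_missing_allow
  }
  pass <- logical(m)
  for (j in seq_len(m)) {
    wins <- max(1L, j - W + 1L):min(j, nw)
    pass[j] <- mean(hom_w[wins]) >= p$window_hit_threshold
  }
  segs <- list()
  j <- 1L
  while (j <= m) {
    if (!pass[j]) { j <- j + 1L; next }
    k <- j
    while (k < m && pass[k + 1L]) k <- k + 1L
    run <- j:k
    hom_idx <- run[!is.na(gt[run]) & gt[run] != 1L]
    if (length(hom_idx)) {
      idx <- hom_idx[1]:hom_idx[length(hom_idx)]
      # split at big gaps
      pieces <- list(); cur <- idx[1]
      if (length(idx) > 1) for (t in 2:length(idx)) {
        if (pos[idx[t]] - pos[idx[t - 1]] > p$max_internal_gap_kb * 1000) {
          pieces[[length(pieces) + 1L]] <- cur
          cur <- idx[t]
        } else cur <- c(cur, idx[t])
      }
      pieces[[length(pieces) + 1L]] <- cur
      for (pc in pieces) {
        span <- pos[pc[length(pc)]] - pos[pc[1]] + 1
        if (span >= p$min_kb * 1000 && length(pc) >= p$min_snps &&
            span / 1000 / length(pc) <= p$density_kb_per_snp) {
          segs[[length(segs) + 1L]] <-
            data.frame(start = pos[pc[1]] - 1, end = pos[pc[length(pc)]],
                       n_snps = length(pc))
        }
      }
    }
    j <- k + 1L
  }
  if (!length(segs)) return(data.frame(start = numeric(0), end = numeric(0),
                                       n_snps = integer(0)))
  do.call(rbind, segs)
}

# exhaustive-pair greedy LD pruning (SNP-count windows)
oracle_ld_prune <- function(geno, pos, window, step, r2max) {
  m <- nrow(geno)
  kept <- rep(TRUE, m)
  for (ws in seq(1L, m, by = step)) {
    we <- min(ws + window - 1L, m)
    for (i in ws:we) {
      if (!kept[i]) next
      if (i + 1L > we) next
      for (jj in (i + 1L):we) {
        if (!kept[jj]) next
        x <- geno[i, ]; y <- geno[jj, ]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 2) next
        if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
        r <- stats::cor(x[ok], y[ok])
        if (r * r > r2max) kept[jj] <- FALSE
      }
    }
  }
  which(kept)
}

# exhaustive max over all 2^m state paths of the two-state ROH HMM;
# returns the maximum log score and whether a given ROH indicator path
# attains it
oracle_hmm_best <- function(gt, pos, h) {
  m <- length(gt)
  is_het <- !is.na(gt) & gt == 1L
  is_obs <- !is.na(gt)
  emis <- function(state, i) {
    if (!is_obs[i]) return(0)
    p <- if (state == 1L) h$p_het_in_roh else h$p_het_outside
    if (is_het[i]) log(p) else log(1 - p)
  }
  pi1 <- h$mean_roh_len / (h$mean_roh_len + h$mean_non_roh_len)
  best <- -Inf
  best_paths <- list()
  for (mask in 0:(2^m - 1)) {
    st <- as.integer(intToBits(mask))[1:m] + 1L  # 1 = non?; map below
    # bit 1 -> state 1 (ROH), bit 0 -> state 2
    st <- ifelse(st == 2L, 1L, 2L)
    sc <- (if (st[1] == 1L) log(pi1) else log(1 - pi1)) + emis(st[1], 1L)
    if (m > 1) for (i in 2:m) {
      d <- pos[i] - pos[i - 1]
      stay <- if (st[i - 1] == 1L) exp(-d / h$mean_roh_len) else
        exp(-d / h$mean_non_roh_len)
      sc <- sc + (if (st[i] == st[i - 1]) log(stay) else log(1 - stay)) +
        emis(st[i], i)
    }
    if (sc > best + 1e-12) { best <- sc; best_paths <- list(st) }
    else if (abs(sc - best) <= 1e-12) best_paths[[length(best_paths) + 1L]] <- st
  }
  list(score = best, paths = best_paths)
}

# sort-and-scan contig N50
oracle_n50 <- function(seg_lens) {
  s <- sort(seg_lens, decreasing = TRUE)
  half <- sum(s) / 2
  acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= half) return(x)
  }
  NA_real_
}

# score of an ROH indicator path under the HMM (for Viterbi optimality)
oracle_hmm_score <- function(st, gt, pos, h) {
  m <- length(gt)
  is_het <- !is.na(gt) & gt == 1L
  is_obs <- !is.na(gt)
  emis <- function(state, i) {
    if (!is_obs[i]) return(0)
    p <- if (state == 1L) h$p_het_in_roh else h$p_het_outside
    if (is_het[i]) log(p) else log(1 - p)
  }
  pi1 <- h$mean_roh_len / (h$mean_roh_len + h$mean_non_roh_len)
  sc <- (if (st[1] == 1L) log(pi1) else log(1 - pi1)) + emis(st[1], 1L)
  if (m > 1) for (i in 2:m) {
    d <- pos[i] - pos[i - 1]
    stay <- if (st[i - 1] == 1L) exp(-d / h$mean_roh_len) else
      exp(-d / h$mean_non_roh_len)
    sc <- sc + (if (st[i] == st[i - 1]) log(stay) else log(1 - stay)) +
      emis(st[i], i)
  }
  sc
}

# reconstruct the ROH-state indicator path implied by returned segments
path_from_segments <- function(segs, pos) {
  st <- rep(2L, length(pos))
  for (i in seq_len(nrow(segs)))
    st[pos > segs$start[i] & pos <= segs$end[i]] <- 1L
  st
}
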