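#' Degrade a reference by random N-run insertion
#'
#' Replaces `gap_len` consecutive bases with 'N' at `n_insertions` uniformly
#' chosen positions (replacement, not insertion, so all downstream
#' coordinates are preserved across the contiguity ladder). Overlapping or
#' adjacent N runs coalesce in the gap map; the contiguous segments between
#' N runs define the contigs used by [contig_stats()].
#'
#' @param ref a `roh_reference` (may already contain gaps from a previous
#'   cycle).
#' @param n_insertions number of N runs to add.
#' @param gap_len length of each N run, bases (default 300).
#' @param seed integer seed.
#' @param gapmap optional existing gap map to extend (0-based half-open
#'   data.frame `contig`, `start`, `end`); when supplied, new insertion
#'   positions avoid existing gaps.
#' @param keep_sequence materialise the gapped sequence (set FALSE to track
#'   only the gap map, e.g. inside [fragment_to_ladder()]).
#' @return List with `ref` (gapped `roh_reference`, or the input when
#'   `keep_sequence = FALSE`) and `gapmap`.
#' @export
insert_gaps <- function(ref, n_insertions, gap_len = 300, seed = 1L,
                        gapmap = NULL, keep_sequence = TRUE) {
  if (gap_len < 1) stop_config("gap_len must be >= 1")
  clens <- ref_lengths(ref)
  if (is.null(gapmap)) gapmap <- empty_intervals()
  existing_n <- interval_total_len(gapmap)
  if (n_insertions * gap_len > sum(clens) - existing_n)
    stop_config("n_insertions exceeds genome capacity")
  if (n_insertions > 0) {
    new_iv <- with_seed(child_seed(seed, "gaps", n_insertions), {
      ct_pick <- sample(names(clens), n_insertions, replace = TRUE,
                        prob = clens)
      starts <- floor(runif(n_insertions, 0, clens[ct_pick] - gap_len + 1))
      data.frame(contig = ct_pick, start = starts, end = starts + gap_len,
                 stringsAsFactors = FALSE)
    })
    gapmap <- merge_gap_runs(rbind(gapmap, new_iv))
  }
  out_ref <- ref
  if (keep_sequence && nrow(gapmap) > 0) {
    for (ct in unique(gapmap$contig)) {
      iv <- gapmap[gapmap$contig == ct, , drop = FALSE]
      r <- charToRaw(ref$contigs[[ct]])
      pos <- unlist(mapply(function(s, e) seq.int(s + 1L, e), iv$start,
                           iv$end, SIMPLIFY = FALSE))
      r[pos] <- charToRaw("N")
      out_ref$contigs[[ct]] <- rawToChar(r)
    }
  }
  list(ref = out_ref, gapmap = gapmap)
}

# coalesce overlapping/adjacent runs per contig
merge_gap_runs <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  out <- lapply(split(iv, iv$contig), function(x) {
    ir <- IRanges::reduce(IRanges::IRanges(start = x$start + 1L, end = x$end))
    data.frame(contig = x$contig[1], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  sort_intervals(df)
}

# lengths of non-N segments implied by a gap map
segment_lengths <- function(clens, gapmap) {
  unlist(lapply(names(clens), function(ct) {
    iv <- gapmap[gapmap$contig == ct, , drop = FALSE]
    comp <- complement_intervals(iv, clens[[ct]])
    comp$end - comp$start
  }))
}

#' Contiguity statistics (contig N50, maximum contig)
#'
#' N50 is the length of the segment at which the descending cumulative sum
#' of segment lengths first reaches half the total non-N length.
#'
#' @param x a `roh_reference` (N runs are located by scanning the
#'   sequence), or a list `list(clens = <named lengths>, gapmap = <gap
#'   map>)` as produced inside [fragment_to_ladder()].
#' @return List with `contig_n50`, `max_contig`, `n_contigs`,
#'   `total_non_n`.
#' @export
contig_stats <- function(x) {
  if (inherits(x, "roh_reference")) {
    segs <- unlist(lapply(x$contigs, function(s) {
      r <- charToRaw(s)
      isn <- r == charToRaw("N")
      if (!any(isn)) return(length(r))
      rl <- rle(as.vector(isn))
      rl$lengths[!rl$values]
    }))
  } else {
    segs <- segment_lengths(x$clens, x$gapmap)
  }
  segs <- segs[segs > 0]
  if (!length(segs)) stop_config("reference contains no non-N sequence")
  s <- sort(segs, decreasing = TRUE)
  n50 <- s[which(cumsum(s) >= sum(s) / 2)[1]]
  list(contig_n50 = unname(n50), max_contig = unname(s[1]),
       n_contigs = length(s), total_non_n = sum(s))
}

#' Build a descending contig-N50 ladder by iterative N insertion
#'
#' Repeats [insert_gaps()] cycles (each cycle adds roughly one gap per
#' current contig, halving the N50), snapshotting the gap map after every
#' cycle, then returns for each target the snapshot whose achieved N50 is
#' closest in log space; an achieved N50 more than a factor 2 from its
#' target is an error.
#'
#' @param ref a `roh_reference` (ungapped).
#' @param targets descending vector of target N50 values, bases.
#' @param gap_len N-run length, bases.
#' @param seed integer seed.
#' @param keep_sequences materialise a gapped `roh_reference` per level
#'   (default FALSE: levels carry the gap map and stats only; coordinates
#'   are preserved, so downstream analysis needs only the gap map).
#' @param max_cycles safety bound on insertion cycles.
#' @return List of levels, each `list(target, achieved_n50, stats, gapmap,
#'   ref)` (`ref` is NULL unless `keep_sequences`).
#' @export
fragment_to_ladder <- function(ref, targets, gap_len = 300, seed = 1L,
                               keep_sequences = FALSE, max_cycles = 40L) {
  if (is.unsorted(rev(targets), strictly = FALSE))
    stop_config("targets must be descending")
  clens <- ref_lengths(ref)
  if (min(targets) < 5 * gap_len)
    stop_config("smallest target is below the gap-spacing resolution")
  snaps <- list(list(gapmap = empty_intervals(),
                     stats = contig_stats(list(clens = clens,
                                               gapmap = empty_intervals()))))
  gm <- empty_intervals()
  cycle <- 0L
  while (cycle < max_cycles) {
    st <- snaps[[length(snaps)]]$stats
    if (st$contig_n50 <= min(targets) / 1.5) break
    cycle <- cycle + 1L
    n_new <- max(1L, st$n_contigs)
    step <- insert_gaps(ref, n_new, gap_len = gap_len,
                        seed = child_seed(seed, "cycle", cycle),
                        gapmap = gm, keep_sequence = FALSE)
    gm <- step$gapmap
    snaps[[length(snaps) + 1L]] <-
      list(gapmap = gm, stats = contig_stats(list(clens = clens, gapmap = gm)))
  }
  achieved <- vapply(snaps, function(s) s$stats$contig_n50, numeric(1))
  lapply(targets, function(tg) {
    k <- which.min(abs(log(achieved) - log(tg)))
    if (achieved[k] > 2 * tg || achieved[k] < tg / 2)
      stop_config("no ladder snapshot within a factor 2 of target %g", tg)
    lv <- snaps[[k]]
    rf <- NULL
    if (keep_sequences) {
      rf <- insert_gaps(ref, 0L, gap_len = gap_len, gapmap = lv$gapmap,
                        keep_sequence = TRUE)$ref
    }
    list(target = tg, achieved_n50 = achieved[k], stats = lv$stats,
         gapmap = lv$gapmap, ref = rf)
  })
}

#' Fragmentation effect model on called genotypes
#'
#' Phenomenological error channel of a fragmented reference: sites falling
#' inside an N run are omitted (missing), and sites within `edge_window`
#' bases of a gap boundary are miscalled (hom flipped to het, het to a
#' random homozygote) with probability `edge_err`.
#'
#' @param edge_window bases around each gap boundary exposed to errors.
#' @param edge_err per-site miscall probability within the edge window.
#' @return An object of class `roh_frag_effect`.
#' @export
frag_effect <- function(edge_window = 5000, edge_err = 0.02) {
  if (edge_err < 0 || edge_err > 1) stop_config("edge_err must be in [0,1]")
  structure(list(edge_window = edge_window, edge_err = edge_err),
            class = "roh_frag_effect")
}

#' Apply reference-fragmentation errors to a call set
#'
#' Coordinates are shared between the intact and gapped references (gaps
#' replace bases), so the gap map applies directly: in-gap sites become
#' missing, near-gap sites are flipped hom/het with probability
#' `fe$edge_err`.
#'
#' @param cg a `roh_calls`.
#' @param gapmap gap map data.frame (`contig`, `start`, `end`).
#' @param fe a [frag_effect()].
#' @param seed integer seed.
#' @return A modified `roh_calls`.
#' @export
apply_fragmentation <- function(cg, gapmap, fe = frag_effect(), seed = 1L) {
  if (nrow(gapmap) == 0L) return(cg)
  gapmap <- merge_gap_runs(gapmap)   # tolerate overlapping runs
  out <- cg
  with_seed(child_seed(seed, "frag", nrow(gapmap)), {
    for (ct in unique(cg$sites$contig)) {
      iv <- gapmap[gapmap$contig == ct, , drop = FALSE]
      if (nrow(iv) == 0L) next
      sel <- which(cg$sites$contig == ct)
      pos <- cg$sites$pos[sel]
      # in-gap: 0-based half-open [start, end) -> 1-based (start, end]
      bnd <- sort(c(iv$start, iv$end))
      k <- findInterval(pos - 0.5, sort(c(iv$start, iv$end)))
      in_gap <- k %% 2L == 1L
      # distance to the nearest gap boundary
      edges <- sort(unique(c(iv$start, iv$end)))
      nearest <- findInterval(pos, edges)
      d_lo <- ifelse(nearest >= 1, pos - edges[pmax(nearest, 1L)], Inf)
      d_hi <- ifelse(nearest < length(edges),
                     edges[pmin(nearest + 1L, length(edges))] - pos, Inf)
      near <- !in_gap & pmin(d_lo, d_hi) <= fe$edge_window
      g <- out$gt[sel]
      flip <- near & !is.na(g) & runif(length(pos)) < fe$edge_err
      hom <- flip & g != 1L
      het <- flip & g == 1L
      g[hom] <- 1L
      g[het] <- sample(c(0L, 2L), sum(het), replace = TRUE)
      g[in_gap] <- NA_integer_
      out$gt[sel] <- g
      out$dp[sel][in_gap] <- 0L
    }
  })
  out
}

#' Emulate a diverged (related-species) reference
#'
#' Substitutes bases at `subst_rate` and cuts the genome at `n_breakpoints`
#' random positions, shuffling segment order and orientation ("mosaic-like
#' collinearity"). The returned effect map is what downstream analysis
#' consumes: apparent genotype noise proportional to the substitution rate
#' plus an implied gap map (zero-width breaks) at the breakpoints, which
#' makes a diverged reference behave like a fragmented one.
#'
#' @param ref a `roh_reference`.
#' @param subst_rate per-base substitution rate in `[0, 0.05]`.
#' @param n_breakpoints number of rearrangement breakpoints (>= 0).
#' @param seed integer seed.
#' @param break_halo half-width in bases of the mapping dead zone implied
#'   by each breakpoint: reads spanning a rearrangement junction cannot map
#'   consistently within roughly a fragment length, so each implied gap
#'   covers the junction plus/minus `break_halo`.
#' @return List with `ref` (the rearranged, substituted reference; contigs
#'   are the shuffled segments) and `effect`
#'   (`roh_divergence_effect`: `subst_rate`, `implied_gapmap`,
#'   `n_breakpoints`), with the gap map in original coordinates.
#' @export
diverge_reference <- function(ref, subst_rate, n_breakpoints, seed = 1L,
                              break_halo = 500) {
  if (subst_rate < 0 || subst_rate > 0.05)
    stop_config("subst_rate must be in [0, 0.05]")
  if (n_breakpoints < 0) stop_config("n_breakpoints must be >= 0")
  clens <- ref_lengths(ref)
  with_seed(child_seed(seed, "diverge", n_breakpoints), {
    new_ref <- ref
    if (subst_rate > 0) {
      bases <- c("A", "C", "G", "T")
      for (ct in names(clens)) {
        n <- rbinom(1, clens[[ct]], subst_rate)
        if (n == 0) next
        pos <- sample.int(clens[[ct]], n)
        cur <- ref_base_at(new_ref$contigs[[ct]], pos)
        shift <- sample.int(3L, n, replace = TRUE)
        repl <- bases[((match(cur, bases) - 1L + shift) %% 4L) + 1L]
        new_ref$contigs[[ct]] <- seq_replace_at(new_ref$contigs[[ct]], pos, repl)
      }
    }
    bp <- empty_intervals()
    if (n_breakpoints > 0) {
      ct_pick <- sample(names(clens), n_breakpoints, replace = TRUE,
                        prob = clens)
      at <- floor(runif(n_breakpoints, 1, clens[ct_pick]))
      bp <- sort_intervals(data.frame(contig = ct_pick,
                                      start = pmax(at - break_halo, 0),
                                      end = pmin(at + break_halo,
                                                 clens[ct_pick]),
                                      stringsAsFactors = FALSE))
      # cut and shuffle: contigs of the diverged reference are the segments
      segs <- list()
      for (ct in names(clens)) {
        cuts <- sort(at[ct_pick == ct])
        b <- c(0, cuts, clens[[ct]])
        for (i in seq_len(length(b) - 1L)) {
          if (b[i + 1] > b[i])
            segs[[length(segs) + 1L]] <-
              substring(new_ref$contigs[[ct]], b[i] + 1, b[i + 1])
        }
      }
      ord <- sample(length(segs))
      flip <- runif(length(segs)) < 0.5
      segs <- lapply(seq_along(segs), function(i) {
        s <- segs[[ord[i]]]
        if (flip[i])
          s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
        s
      })
      new_ref <- roh_reference(setNames(unlist(segs),
                                        sprintf("seg%03d", seq_along(segs))))
    }
    list(ref = new_ref,
         effect = structure(list(subst_rate = subst_rate,
                                 implied_gapmap = bp,
                                 n_breakpoints = n_breakpoints),
                            class = "roh_divergence_effect"))
  })
}

#' Apply divergence effects to a call set
#'
#' Genome-wide genotype noise at the substitution rate plus the
#' fragmentation channel at the implied breakpoints.
#'
#' @param cg a `roh_calls`.
#' @param effect a `roh_divergence_effect` from [diverge_reference()].
#' @param fe a [frag_effect()] controlling the breakpoint edge channel.
#' @param seed integer seed.
#' @return A modified `roh_calls`.
#' @export
apply_divergence <- function(cg, effect, fe = frag_effect(), seed = 1L) {
  out <- cg
  if (effect$subst_rate > 0) {
    with_seed(child_seed(seed, "divnoise"), {
      g <- out$gt
      flip <- !is.na(g) & runif(length(g)) < effect$subst_rate
      hom <- flip & g != 1L
      het <- flip & g == 1L
      g[hom] <- 1L
      g[het] <- sample(c(0L, 2L), sum(het), replace = TRUE)
      out$gt <- g
    })
  }
  if (nrow(effect$implied_gapmap) > 0)
    out <- apply_fragmentation(out, effect$implied_gapmap, fe,
                               seed = child_seed(seed, "divfrag"))
  out
}

#' Write a ladder's contiguity table as TSV
#'
#' One row per level: target and achieved N50, maximum contig, contig
#' count.
#'
#' @param ladder result of [fragment_to_ladder()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ladder_tsv <- function(ladder, path) {
  df <- do.call(rbind, lapply(seq_along(ladder), function(i) {
    lv <- ladder[[i]]
    data.frame(level = i, target_n50 = lv$target,
               achieved_n50 = lv$achieved_n50,
               max_contig = lv$stats$max_contig,
               n_contigs = lv$stats$n_contigs)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
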