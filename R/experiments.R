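#' Generate the full benchmark population in one call
#'
#' Reference, planted population and per-individual haplotype pairs, all
#' derived from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return List with `ref`, `pop` (`roh_population`) and `hps` (named list
#'   of `roh_haplotypes`).
#' @export
bench_population <- function(cfg) {
  ref <- make_reference(cfg)
  pop <- plant_population(ref, cfg)
  ids <- names(pop$truth)
  hps <- lapply(ids, function(id)
    build_haplotypes(ref, pop$variants, id,
                     seed = child_seed(cfg$seed, "hap", id)))
  names(hps) <- ids
  list(ref = ref, pop = pop, hps = hps)
}

# one sweep cell: per-individual pipeline + metrics rows
cell_rows <- function(calls_list, pop, total_len, params, merge, overlap_q,
                      vs_for_prune = NULL) {
  pop_vs <- NULL
  if (!is.na(params$prune_r2))
    pop_vs <- vs_for_prune %||%
      calls_to_variants(calls_list, pop$variants$sites)
  rows <- lapply(names(calls_list), function(id) {
    r <- tryCatch({
      segs <- call_pipeline(calls_list[[id]], params, pop_vs = pop_vs,
                            merge = merge)
      mr <- metrics_report(segs, pop$truth[[id]], total_len,
                           called = calls_list[[id]], vs = pop$variants,
                           individual = id, overlap_q = overlap_q)
      mr$error <- NA_character_
      mr
    }, error = function(e) {
      data.frame(f_roh_true = NA_real_, f_roh_detected = NA_real_,
                 f_roh_error_ratio = NA_real_, n_segments = NA_integer_,
                 n_truth_segments = NA_integer_, mean_roh_len = NA_real_,
                 mean_roh_len_true = NA_real_, total_roh_len = NA_real_,
                 snp_error_ratio = NA_real_, snp_missing_rate = NA_real_,
                 detection_ratio = NA_real_,
                 n_class_1 = NA_integer_, n_class_2 = NA_integer_,
                 n_class_3 = NA_integer_, n_class_4 = NA_integer_,
                 n_class_5 = NA_integer_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    r$individual <- id
    r$f_roh_target <- unname(pop$targets[id])
    r
  })
  do.call(rbind, rows)
}

pileup_population <- function(reads_list, pop, hps, cc, seed) {
  lapply(names(reads_list), function(id)
    pileup_call(reads_list[[id]], pop$variants$sites, hps[[id]], cc,
                seed = child_seed(seed, "call", id))) |>
    setNames(names(reads_list))
}

#' Depth-response sweep
#'
#' Plants one population per replicate seed, simulates reads once at the
#' maximum depth of the axis, derives every lower depth by random read
#' thinning (preserving across-depth correlation), calls ROH and reports
#' per-cell metrics.
#'
#' @param depths depth axis in fold-coverage (the benchmark's full axis is
#'   2, 2.5, 3, 3.5, 4, 5, 6, 8, 10, 12, 15, 20, 30, 60, 100).
#' @param cfg a [sim_config()].
#' @param params a [roh_params()].
#' @param cc a [call_config()].
#' @param read_len read length, bases.
#' @param seeds replicate seeds (distinct integers).
#' @param merge apply gap-merging.
#' @param overlap_q detection-ratio threshold.
#' @return A data.frame of class `roh_sweep`, one row per
#'   (seed, depth, individual).
#' @export
run_depth_sweep <- function(depths, cfg = sim_config(),
                            params = roh_params(), cc = call_config(),
                            read_len = 100L, seeds = 1:3, merge = TRUE,
                            overlap_q = 0.9) {
  if (!length(depths)) stop_config("need at least one depth")
  if (anyDuplicated(seeds)) stop_config("replicate seeds must be distinct")
  dmax <- max(depths)
  out <- list()
  for (s in seeds) {
    rep_cfg <- cfg
    rep_cfg$seed <- child_seed(cfg$seed, "rep", s)
    bench <- bench_population(rep_cfg)
    total_len <- ref_total_len(bench$ref)
    reads_max <- lapply(bench$hps, function(hp)
      simulate_reads(hp, dmax, read_len = read_len,
                     seed = child_seed(rep_cfg$seed, "sim")))
    for (d in depths) {
      reads_d <- if (d == dmax) reads_max else
        lapply(reads_max, subsample_depth, fraction = d / dmax,
               seed = child_seed(rep_cfg$seed, "thin", round(100 * d)))
      calls <- pileup_population(reads_d, bench$pop, bench$hps, cc,
                                 seed = child_seed(rep_cfg$seed, "pu",
                                                   round(100 * d)))
      rows <- cell_rows(calls, bench$pop, total_len, params, merge, overlap_q)
      rows$depth <- d
      rows$realized_depth <- mean(vapply(names(reads_d), function(id)
        realized_depth(reads_d[[id]], bench$hps[[id]]), numeric(1)))
      rows$seed <- s
      out[[length(out) + 1L]] <- rows
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  class(df) <- c("roh_sweep", "data.frame")
  attr(df, "group") <- "depth"
  df
}

#' Contiguity (contig-N50) sweep at fixed depth
#'
#' Builds an N50 ladder per replicate, applies the fragmentation error
#' channel to one fixed set of calls at `depth`, and reports metrics with
#' and without gap-merging.
#'
#' @param n50_targets descending N50 targets in bases.
#' @param depth sequencing depth (the benchmark uses 20).
#' @param cfg,params,cc,read_len,seeds,overlap_q as in
#'   [run_depth_sweep()].
#' @param fe a [frag_effect()].
#' @return A `roh_sweep` data.frame, one row per
#'   (seed, level, gap_merged, individual).
#' @export
run_n50_sweep <- function(n50_targets, depth = 20, cfg = sim_config(),
                          params = roh_params(), cc = call_config(),
                          fe = frag_effect(), read_len = 100L, seeds = 1:3,
                          overlap_q = 0.9) {
  out <- list()
  for (s in seeds) {
    rep_cfg <- cfg
    rep_cfg$seed <- child_seed(cfg$seed, "rep", s)
    bench <- bench_population(rep_cfg)
    total_len <- ref_total_len(bench$ref)
    reads <- lapply(bench$hps, function(hp)
      simulate_reads(hp, depth, read_len = read_len,
                     seed = child_seed(rep_cfg$seed, "sim")))
    calls0 <- pileup_population(reads, bench$pop, bench$hps, cc,
                                seed = child_seed(rep_cfg$seed, "pu"))
    ladder <- fragment_to_ladder(bench$ref, n50_targets,
                                 seed = child_seed(rep_cfg$seed, "ladder"))
    for (li in seq_along(ladder)) {
      lv <- ladder[[li]]
      calls <- lapply(names(calls0), function(id)
        apply_fragmentation(calls0[[id]], lv$gapmap, fe,
                            seed = child_seed(rep_cfg$seed, "fx", li, id)))
      names(calls) <- names(calls0)
      for (mg in c(TRUE, FALSE)) {
        rows <- cell_rows(calls, bench$pop, total_len, params, mg, overlap_q)
        rows$level <- li
        rows$target_n50 <- lv$target
        rows$achieved_n50 <- lv$achieved_n50
        rows$gap_merged <- mg
        rows$depth <- depth
        rows$seed <- s
        out[[length(out) + 1L]] <- rows
      }
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  class(df) <- c("roh_sweep", "data.frame")
  attr(df, "group") <- "n50"
  df
}

#' Read-length sweep at fixed depth
#'
#' One cell per read length, holding the population and replicate seed
#' fixed across lengths so the comparison is paired.
#'
#' @param read_lens read lengths in bases (benchmark panel: 30, 50, 75,
#'   100, 150).
#' @param depth sequencing depth (the benchmark uses 20).
#' @param cfg,params,cc,seeds,merge,overlap_q as in [run_depth_sweep()].
#' @return A `roh_sweep` data.frame, one row per
#'   (seed, read_len, individual).
#' @export
run_readlen_sweep <- function(read_lens = c(30L, 50L, 75L, 100L, 150L),
                              depth = 20, cfg = sim_config(),
                              params = roh_params(), cc = call_config(),
                              seeds = 1:3, merge = TRUE, overlap_q = 0.9) {
  out <- list()
  for (s in seeds) {
    rep_cfg <- cfg
    rep_cfg$seed <- child_seed(cfg$seed, "rep", s)
    bench <- bench_population(rep_cfg)
    total_len <- ref_total_len(bench$ref)
    for (rl in read_lens) {
      reads <- lapply(bench$hps, function(hp)
        simulate_reads(hp, depth, read_len = rl,
                       seed = child_seed(rep_cfg$seed, "sim")))
      calls <- pileup_population(reads, bench$pop, bench$hps, cc,
                                 seed = child_seed(rep_cfg$seed, "pu", rl))
      rows <- cell_rows(calls, bench$pop, total_len, params, merge, overlap_q)
      rows$read_len <- rl
      rows$depth <- depth
      rows$realized_depth <- mean(vapply(names(reads), function(id)
        realized_depth(reads[[id]], bench$hps[[id]]), numeric(1)))
      rows$seed <- s
      out[[length(out) + 1L]] <- rows
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  class(df) <- c("roh_sweep", "data.frame")
  attr(df, "group") <- "readlen"
  df
}

#' Parameter-optimisation grid at a fixed degraded condition
#'
#' Evaluates a set of caller parameterisations on one fixed condition
#' (default 5x depth, the depth commonly recommended for low-quality
#' samples) and ranks them by mean absolute F_ROH error ratio.
#'
#' @param param_list named list of [roh_params()] objects (e.g. axis-wise
#'   variations of the pruning window, r-squared threshold, window size and
#'   minimum SNP count).
#' @param depth sequencing depth of the degraded condition.
#' @param cfg,cc,read_len,seeds,merge,overlap_q as in [run_depth_sweep()].
#' @return A `roh_sweep` data.frame with a `param` column; attribute
#'   `ranking` holds mean |F_ROH error ratio| and mean-length error per
#'   parameterisation (best first), attribute `best` its first name.
#' @export
run_param_grid <- function(param_list, depth = 5, cfg = sim_config(),
                           cc = call_config(), read_len = 100L, seeds = 1:3,
                           merge = TRUE, overlap_q = 0.9) {
  if (!length(param_list)) stop_config("empty parameter grid")
  if (is.null(names(param_list)) || any(names(param_list) == ""))
    stop_config("param_list must be named")
  out <- list()
  for (s in seeds) {
    rep_cfg <- cfg
    rep_cfg$seed <- child_seed(cfg$seed, "rep", s)
    bench <- bench_population(rep_cfg)
    total_len <- ref_total_len(bench$ref)
    reads <- lapply(bench$hps, function(hp)
      simulate_reads(hp, depth, read_len = read_len,
                     seed = child_seed(rep_cfg$seed, "sim")))
    calls <- pileup_population(reads, bench$pop, bench$hps, cc,
                               seed = child_seed(rep_cfg$seed, "pu"))
    vs_called <- calls_to_variants(calls, bench$pop$variants$sites)
    for (pn in names(param_list)) {
      rows <- cell_rows(calls, bench$pop, total_len, param_list[[pn]],
                        merge, overlap_q, vs_for_prune = vs_called)
      rows$param <- pn
      rows$depth <- depth
      rows$seed <- s
      out[[length(out) + 1L]] <- rows
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  abs_err <- tapply(abs(df$f_roh_error_ratio), df$param, mean, na.rm = TRUE)
  len_err <- tapply(abs(df$mean_roh_len / df$mean_roh_len_true - 1),
                    df$param, mean, na.rm = TRUE)
  ranking <- data.frame(param = names(abs_err),
                        mean_abs_f_error = as.numeric(abs_err),
                        mean_abs_len_error = as.numeric(len_err[names(abs_err)]),
                        row.names = NULL)
  ranking <- ranking[order(ranking$mean_abs_f_error), , drop = FALSE]
  class(df) <- c("roh_sweep", "data.frame")
  attr(df, "group") <- "param_grid"
  attr(df, "ranking") <- ranking
  attr(df, "best") <- ranking$param[1]
  df
}

#' Named caller parameter presets
#'
#' Published parameter recommendations: `plink_default` (the tool's stock
#' settings), `lowdepth` (for ~5x data: pruning window 50 SNPs / step 1 /
#' r2 0.8, scan window 80 SNPs, minimum 150 SNPs), `lowdepth_highF` (scan
#' window 70 for highly inbred individuals) and `fragmented_ref` (scan
#' window 12, within the 10-15 range advised for contig N50 < 100 kb).
#'
#' @param name optional preset name; omit for the full named list.
#' @return A [roh_params()] or a named list of them.
#' @export
presets <- function(name = NULL) {
  p <- list(
    plink_default = roh_params(window_snps = 50L, min_snps = 100L,
                               min_kb = 1000),
    lowdepth = roh_params(prune_window = 50L, prune_step = 1L,
                          prune_r2 = 0.8, window_snps = 80L,
                          min_snps = 150L, min_kb = 500),
    lowdepth_highF = roh_params(prune_window = 50L, prune_step = 1L,
                                prune_r2 = 0.8, window_snps = 70L,
                                min_snps = 150L, min_kb = 500),
    fragmented_ref = roh_params(prune_window = 50L, prune_step = 1L,
                                prune_r2 = 0.8, window_snps = 12L,
                                min_snps = 150L, min_kb = 500))
  if (is.null(name)) return(p)
  if (!name %in% names(p)) stop_config("unknown preset '%s'", name)
  p[[name]]
}
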