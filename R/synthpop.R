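#' Generator configuration for synthetic inbred populations
#'
#' Bundles every knob of the synthetic-data generator: genome shape,
#' SNP densities, the planted ROH length mix and the target inbreeding
#' ladder. The defaults are the benchmark's study conditions: two contigs,
#' a heterozygosity rate of 1e-3 per base outside ROH (typical of a
#' mammalian genome), homozygous-alternative SNPs at the same rate
#' genome-wide, and the eight-individual inbreeding ladder spanning
#' F_ROH ~ 5.7%-47.7%.
#'
#' @param n_contigs number of contigs ("autosomes") to simulate.
#' @param contig_len contig length in bases.
#' @param het_rate_theta heterozygous SNPs per base outside ROH.
#' @param hom_alt_rate_phi homozygous-alternative SNPs per base, genome-wide
#'   (ROH must contain homozygous SNPs to be visible to a window caller).
#' @param roh_length_mix data.frame with columns `min_mb`, `max_mb`,
#'   `weight`: the planted ROH length classes. Classes that do not fit the
#'   contig length are dropped and weights renormalised. Defaults mirror the
#'   reporting classes 0.5-1, 1-5, 5-10, 10-25 and >25 Mb.
#' @param target_f_roh_levels fractions in (0, 0.95): one individual is
#'   planted per level.
#' @param min_roh_len minimum planted (and counted) ROH length, bases.
#' @param min_roh_gap minimum distance between planted ROH, bases. Keeps
#'   truth segments resolvable under the 500 kb gap-merge rule.
#' @param f_tol placement tolerance on F_ROH, as a fraction of genome length.
#' @param seed integer master seed; all generator randomness derives from it.
#' @return An object of class `roh_sim_config`.
#' @export
sim_config <- function(n_contigs = 2L,
                       contig_len = 10e6,
                       het_rate_theta = 1e-3,
                       hom_alt_rate_phi = het_rate_theta,
                       roh_length_mix = NULL,
                       target_f_roh_levels = c(0.0566, 0.1237, 0.1717,
                                               0.2210, 0.2841, 0.3543,
                                               0.3854, 0.4773),
                       min_roh_len = 5e5,
                       min_roh_gap = 6e5,
                       f_tol = 0.005,
                       seed = 1L) {
  if (het_rate_theta <= 0 || het_rate_theta >= 1)
    stop_config("het_rate_theta must be in (0,1)")
  if (hom_alt_rate_phi <= 0 || hom_alt_rate_phi >= 1)
    stop_config("hom_alt_rate_phi must be in (0,1)")
  if (any(target_f_roh_levels < 0 | target_f_roh_levels >= 0.95))
    stop_config("each target F_ROH must be in [0, 0.95)")
  if (is.null(roh_length_mix)) {
    roh_length_mix <- data.frame(
      min_mb  = c(0.5, 1, 5, 10, 25),
      max_mb  = c(1, 5, 10, 25, 40),
      weight  = c(0.30, 0.45, 0.15, 0.07, 0.03))
  }
  if (abs(sum(roh_length_mix$weight) - 1) > 1e-8) {
    roh_length_mix$weight <- roh_length_mix$weight / sum(roh_length_mix$weight)
  }
  structure(list(n_contigs = as.integer(n_contigs),
                 contig_len = contig_len,
                 het_rate_theta = het_rate_theta,
                 hom_alt_rate_phi = hom_alt_rate_phi,
                 roh_length_mix = roh_length_mix,
                 target_f_roh_levels = target_f_roh_levels,
                 min_roh_len = min_roh_len,
                 min_roh_gap = min_roh_gap,
                 f_tol = f_tol,
                 seed = as.integer(seed)),
            class = "roh_sim_config")
}

#' @export
print.roh_sim_config <- function(x, ...) {
  cat(sprintf(paste0("<roh_sim_config> %d x %.1f Mb, theta=%g, phi=%g, ",
                     "%d target F_ROH level(s), seed=%d\n"),
              x$n_contigs, x$contig_len / 1e6, x$het_rate_theta,
              x$hom_alt_rate_phi, length(x$target_f_roh_levels), x$seed))
  invisible(x)
}

#' Multi-sample variant container
#'
#' Sorted biallelic SNP records with per-individual genotypes coded
#' 0 = hom-ref, 1 = het, 2 = hom-alt, NA = missing.
#'
#' @param sites data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`.
#' @param geno integer matrix, one row per site, one column per individual.
#' @return An object of class `roh_variants`.
#' @export
roh_variants <- function(sites, geno) {
  geno <- as.matrix(geno)
  if (nrow(sites) != nrow(geno))
    stop_config("sites and geno row counts differ")
  o <- order(sites$contig, sites$pos)
  sites <- sites[o, , drop = FALSE]
  geno <- geno[o, , drop = FALSE]
  rownames(sites) <- NULL
  rownames(geno) <- NULL
  if (anyDuplicated(paste(sites$contig, sites$pos)))
    stop_config("positions must be unique per contig")
  structure(list(sites = sites, geno = geno), class = "roh_variants")
}

#' @export
print.roh_variants <- function(x, ...) {
  cat(sprintf("<roh_variants> %d site(s) x %d individual(s) on %d contig(s)\n",
              nrow(x$sites), ncol(x$geno), length(unique(x$sites$contig))))
  invisible(x)
}

#' Individuals present in a variant set
#' @param vs a `roh_variants`.
#' @return Character vector of sample names.
#' @export
vs_samples <- function(vs) colnames(vs$geno)

# draw the list of ROH lengths for one individual so the total lands within
# f_tol of the target fraction
draw_roh_lengths <- function(target, total_len, cfg) {
  if (target <= 0) return(numeric(0))
  mix <- cfg$roh_length_mix
  cap <- 0.9 * cfg$contig_len
  fit <- mix$min_mb * 1e6 <= cfg$contig_len / 2
  if (!any(fit)) stop_config("no ROH length class fits the contig length")
  mix <- mix[fit, , drop = FALSE]
  mix$weight <- mix$weight / sum(mix$weight)
  goal <- target * total_len
  tol <- cfg$f_tol * total_len
  if (goal + tol < cfg$min_roh_len)
    stop_config(paste("target F_ROH %.4f asks for %.0f ROH bases, below the",
                      "minimum ROH length %.0f"), target, goal,
                cfg$min_roh_len)
  lens <- numeric(0)
  while (sum(lens) < goal - tol) {
    cls <- sample.int(nrow(mix), 1L, prob = mix$weight)
    len <- runif(1, mix$min_mb[cls] * 1e6, min(mix$max_mb[cls] * 1e6, cap))
    need <- goal - sum(lens)
    if (len > need) {
      if (need >= cfg$min_roh_len) {
        len <- need
      } else if (length(lens) > 0 && lens[length(lens)] + need <= cap) {
        lens[length(lens)] <- lens[length(lens)] + need
        break
      } else {
        len <- cfg$min_roh_len
      }
    }
    lens <- c(lens, len)
  }
  round(lens)
}

# place intervals of the given lengths without overlap, keeping min_roh_gap
# distance; rejection sampling with a bounded retry budget
place_roh <- function(lens, ref, cfg) {
  clens <- ref_lengths(ref)
  placed <- lapply(names(clens), function(x) empty_intervals())
  names(placed) <- names(clens)
  for (len in sort(lens, decreasing = TRUE)) {
    ok <- FALSE
    last_ct <- "?"
    for (try in seq_len(1000L)) {
      ct <- sample(names(clens), 1L, prob = pmax(clens - len, 0))
      last_ct <- ct
      if (clens[[ct]] <= len) next
      s <- floor(runif(1, 0, clens[[ct]] - len))
      e <- s + len
      cur <- placed[[ct]]
      clash <- nrow(cur) > 0 &&
        any(s < cur$end + cfg$min_roh_gap & e > cur$start - cfg$min_roh_gap)
      if (!clash) {
        placed[[ct]] <- rbind(cur, data.frame(contig = ct, start = s, end = e,
                                              stringsAsFactors = FALSE))
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop_config("could not place a %.2f Mb ROH on contig %s after 1000 tries",
                  len / 1e6, last_ct)
  }
  sort_intervals(do.call(rbind, placed))
}

# complement of truth intervals on one contig, 0-based half-open
complement_intervals <- function(iv, clen) {
  if (nrow(iv) == 0L)
    return(data.frame(start = 0, end = clen))
  iv <- iv[order(iv$start), , drop = FALSE]
  starts <- c(0, iv$end)
  ends <- c(iv$start, clen)
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep])
}

#' Plant one individual: ROH truth set plus genotypes
#'
#' Draws ROH intervals from the configured length mix and places them
#' without overlap until the truth inbreeding coefficient is within
#' `cfg$f_tol` of `target_f_roh`; plants heterozygous SNPs as a Poisson
#' process at rate theta strictly outside ROH and homozygous-alternative
#' SNPs at rate phi genome-wide (so ROH contain homozygous SNPs and remain
#' visible to density filters).
#'
#' @param ref a `roh_reference`.
#' @param target_f_roh target inbreeding coefficient in `[0, 0.95)`.
#' @param cfg a [sim_config()].
#' @param seed integer seed (defaults to a stream derived from `cfg$seed`).
#' @param id individual name used in the genotype column.
#' @return A list with `truth` (data.frame `contig`, `start`, `end`;
#'   0-based half-open) and `variants` (single-sample `roh_variants`).
#' @export
plant_individual <- function(ref, target_f_roh, cfg,
                             seed = child_seed(cfg$seed, "ind", round(1e6 * target_f_roh)),
                             id = "ind01") {
  if (target_f_roh < 0 || target_f_roh >= 0.95)
    stop_config("target_f_roh must be in [0, 0.95)")
  total_len <- ref_total_len(ref)
  clens <- ref_lengths(ref)
  with_seed(seed, {
    truth <- empty_intervals()
    if (target_f_roh > 0) {
      for (attempt in seq_len(20L)) {
        lens <- draw_roh_lengths(target_f_roh, total_len, cfg)
        t2 <- try(place_roh(lens, ref, cfg), silent = TRUE)
        if (!inherits(t2, "try-error")) { truth <- t2; break }
        if (attempt == 20L) stop(attr(t2, "condition"))
      }
    }
    sites_list <- list()
    for (ct in names(clens)) {
      tr <- truth[truth$contig == ct, , drop = FALSE]
      comp <- complement_intervals(tr, clens[[ct]])
      # heterozygous SNPs strictly outside ROH
      het_pos <- unlist(lapply(seq_len(nrow(comp)), function(i) {
        w <- comp$end[i] - comp$start[i]
        n <- rpois(1, cfg$het_rate_theta * w)
        if (n == 0L) return(integer(0))
        comp$start[i] + sample.int(w, min(n, w))  # 1-based within [start+1, end]
      }))
      # hom-alt SNPs genome-wide
      n_hom <- rpois(1, cfg$hom_alt_rate_phi * clens[[ct]])
      hom_pos <- if (n_hom > 0) sample.int(clens[[ct]], min(n_hom, clens[[ct]])) else integer(0)
      pos <- as.integer(c(het_pos, hom_pos))
      gt <- rep(c(1L, 2L), c(length(het_pos), length(hom_pos)))
      keep <- !duplicated(pos)   # het record wins on collision
      pos <- pos[keep]; gt <- gt[keep]
      o <- order(pos)
      pos <- pos[o]; gt <- gt[o]
      refb <- ref_base_at(ref$contigs[[ct]], pos)
      alts <- c("A", "C", "G", "T")
      # alt = ref base cyclically shifted by 1..3: uniform over the other three
      shift <- sample.int(3L, length(pos), replace = TRUE)
      alt <- alts[((match(refb, alts) - 1L + shift) %% 4L) + 1L]
      sites_list[[ct]] <- data.frame(contig = ct, pos = pos, ref = refb,
                                     alt = alt, gt = gt,
                                     stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, sites_list)
    rownames(sites) <- NULL
    geno <- matrix(sites$gt, ncol = 1, dimnames = list(NULL, id))
    list(truth = truth,
         variants = roh_variants(sites[, c("contig", "pos", "ref", "alt")],
                                 geno))
  })
}

#' Plant a population of individuals at a ladder of inbreeding levels
#'
#' One individual per target level, merged into a single multi-sample
#' variant set (union of sites; individuals without a record at a site are
#' hom-ref there).
#'
#' @param ref a `roh_reference`.
#' @param cfg a [sim_config()]; one individual is planted per entry of
#'   `cfg$target_f_roh_levels`.
#' @return An object of class `roh_population`: list with `truth` (named
#'   list of truth interval data.frames), `variants` (`roh_variants`),
#'   `targets`, `config`.
#' @export
plant_population <- function(ref, cfg) {
  targets <- cfg$target_f_roh_levels
  if (length(targets) < 1L) stop_config("need at least one target level")
  ids <- sprintf("ind%02d", seq_along(targets))
  ind <- lapply(seq_along(targets), function(i) {
    plant_individual(ref, targets[i], cfg,
                     seed = child_seed(cfg$seed, "ind", i), id = ids[i])
  })
  names(ind) <- ids
  # union of sites across individuals
  all_sites <- do.call(rbind, lapply(ind, function(x) x$variants$sites))
  key <- paste(all_sites$contig, all_sites$pos)
  uniq <- !duplicated(key)      # first-seen ref/alt wins on collisions
  sites <- all_sites[uniq, , drop = FALSE]
  ukey <- key[uniq]
  geno <- matrix(0L, nrow = nrow(sites), ncol = length(ids),
                 dimnames = list(NULL, ids))
  for (i in seq_along(ids)) {
    v <- ind[[i]]$variants
    idx <- match(paste(v$sites$contig, v$sites$pos), ukey)
    geno[idx, i] <- v$geno[, 1]
  }
  structure(list(truth = lapply(ind, `[[`, "truth"),
                 variants = roh_variants(sites, geno),
                 targets = setNames(targets, ids),
                 config = cfg),
            class = "roh_population")
}

#' @export
print.roh_population <- function(x, ...) {
  cat(sprintf("<roh_population> %d individual(s), %d site(s)\n",
              length(x$truth), nrow(x$variants$sites)))
  invisible(x)
}

#' Truth inbreeding coefficient from planted intervals
#'
#' Ratio of the total length of ROH intervals (counting only those at least
#' `min_len` long) to the total reference length.
#'
#' @param truth data.frame of intervals (`contig`, `start`, `end`).
#' @param ref a `roh_reference`.
#' @param min_len minimum interval length counted, bases.
#' @return F_ROH as a fraction in `[0, 1]`.
#' @export
truth_f_roh <- function(truth, ref, min_len = 0) {
  if (nrow(truth) == 0L) return(0)
  clens <- ref_lengths(ref)
  if (!all(truth$contig %in% names(clens)))
    stop_config("truth interval on unknown contig")
  if (any(truth$start < 0) ||
      any(truth$end > clens[truth$contig]))
    stop_config("truth interval out of contig bounds")
  w <- truth$end - truth$start
  sum(w[w >= min_len]) / ref_total_len(ref)
}
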