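#' Build the two haploid sequences of one individual
#'
#' Substitutes an individual's variants into the reference: hom-alt sites
#' carry the alternative allele on both haplotypes; het sites carry it on
#' exactly one haplotype, chosen by a seeded fair coin per site (input
#' genotypes are unphased, and phase is irrelevant to ROH truth); hom-ref
#' and missing sites are left untouched.
#'
#' @param ref a `roh_reference`.
#' @param vs a `roh_variants` containing `individual`.
#' @param individual sample name.
#' @param seed integer seed for the per-site phase coin.
#' @return An object of class `roh_haplotypes`: list with `hapA`, `hapB`
#'   (named character vectors parallel to the reference) and `individual`.
#' @export
build_haplotypes <- function(ref, vs, individual, seed = 1L) {
  if (!individual %in% vs_samples(vs))
    stop_config("individual '%s' not present in variant set", individual)
  gt <- vs$geno[, individual]
  sites <- vs$sites
  # consistency: REF allele must match the reference base
  for (ct in unique(sites$contig)) {
    sel <- sites$contig == ct
    b <- ref_base_at(ref$contigs[[ct]], sites$pos[sel])
    bad <- which(b != sites$ref[sel])
    if (length(bad))
      stop_config("ref allele mismatch at %s:%d (reference %s, record %s)",
                  ct, sites$pos[sel][bad[1]], b[bad[1]],
                  sites$ref[sel][bad[1]])
  }
  hapA <- ref$contigs
  hapB <- ref$contigs
  with_seed(child_seed(seed, "phase", individual), {
    to_a <- runif(nrow(sites)) < 0.5   # one draw per site, any genotype
    for (ct in unique(sites$contig)) {
      sel <- which(sites$contig == ct)
      g <- gt[sel]
      pos <- sites$pos[sel]
      alt <- sites$alt[sel]
      hom <- which(!is.na(g) & g == 2L)
      het <- which(!is.na(g) & g == 1L)
      if (length(hom)) {
        hapA[[ct]] <- seq_replace_at(hapA[[ct]], pos[hom], alt[hom])
        hapB[[ct]] <- seq_replace_at(hapB[[ct]], pos[hom], alt[hom])
      }
      ha <- het[to_a[sel][het]]
      hb <- setdiff(het, ha)
      if (length(ha))
        hapA[[ct]] <- seq_replace_at(hapA[[ct]], pos[ha], alt[ha])
      if (length(hb))
        hapB[[ct]] <- seq_replace_at(hapB[[ct]], pos[hb], alt[hb])
    }
  })
  structure(list(hapA = hapA, hapB = hapB, individual = individual),
            class = "roh_haplotypes")
}

#' @export
print.roh_haplotypes <- function(x, ...) {
  cat(sprintf("<roh_haplotypes> individual %s, %d contig(s), %.3f Mb\n",
              x$individual, length(x$hapA), sum(nchar(x$hapA)) / 1e6))
  invisible(x)
}

#' Recover genotypes by comparing haplotypes to the reference
#'
#' Round-trip validator for [build_haplotypes()]: scans all positions where
#' either haplotype differs from the reference and emits hom-alt where both
#' differ identically, het where exactly one differs.
#'
#' @param ref a `roh_reference`.
#' @param hp a `roh_haplotypes`.
#' @return A single-sample `roh_variants`.
#' @export
rederive_genotypes <- function(ref, hp) {
  out <- list()
  for (ct in names(ref$contigs)) {
    r <- charToRaw(ref$contigs[[ct]])
    a <- charToRaw(hp$hapA[[ct]])
    b <- charToRaw(hp$hapB[[ct]])
    if (length(a) != length(r) || length(b) != length(r))
      stop_config("haplotype length mismatch on contig %s", ct)
    da <- a != r
    db <- b != r
    pos <- which(da | db)
    if (!length(pos)) next
    gt <- ifelse(da[pos] & db[pos], 2L, 1L)
    # alt allele comes from whichever haplotype differs
    alt_raw <- a[pos]
    use_b <- !da[pos]
    alt_raw[use_b] <- b[pos][use_b]
    alt <- rawToChar(alt_raw, multiple = TRUE)
    out[[ct]] <- data.frame(contig = ct, pos = pos,
                            ref = rawToChar(r[pos], multiple = TRUE),
                            alt = alt, gt = gt, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    sites <- data.frame(contig = character(), pos = integer(),
                        ref = character(), alt = character(),
                        stringsAsFactors = FALSE)
    return(roh_variants(sites, matrix(integer(0), ncol = 1,
                                      dimnames = list(NULL, hp$individual))))
  }
  df <- do.call(rbind, out)
  roh_variants(df[, c("contig", "pos", "ref", "alt")],
               matrix(df$gt, ncol = 1, dimnames = list(NULL, hp$individual)))
}

#' Write a haplotype pair as two FASTA files
#'
#' Produces `<individual>.hapA.fa` and `<individual>.hapB.fa` under `dir`.
#'
#' @param hp a `roh_haplotypes`.
#' @param dir output directory.
#' @return Character vector of the two paths, invisibly.
#' @export
write_haplotypes <- function(hp, dir = ".") {
  pa <- file.path(dir, sprintf("%s.hapA.fa", hp$individual))
  pb <- file.path(dir, sprintf("%s.hapB.fa", hp$individual))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(hp$hapA), pa, width = 60L)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(hp$hapB), pb, width = 60L)
  invisible(c(pa, pb))
}
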