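#' Write a variant set as a minimal VCF v4.2
#'
#' CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO/FORMAT columns with diploid
#' unphased GT (and DP when depths are supplied); missing genotypes are
#' `./.`.
#'
#' @param vs a `roh_variants`.
#' @param path output file.
#' @param ref optional `roh_reference` for contig header lines.
#' @param dp optional depth matrix parallel to `vs$geno`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path, ref = NULL, dp = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=rohsim",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  if (!is.null(dp))
    writeLines('##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
               con)
  if (!is.null(ref)) {
    lens <- ref_lengths(ref)
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(lens), lens), con)
  }
  samples <- colnames(vs$geno)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[vs$geno + 1L],
                   nrow = nrow(vs$geno))
  gt_str[is.na(vs$geno)] <- "./."
  if (!is.null(dp)) {
    dp_chr <- matrix(as.character(dp), nrow = nrow(dp))
    dp_chr[is.na(dp)] <- "."
    gt_str <- matrix(paste(gt_str, dp_chr, sep = ":"), nrow = nrow(gt_str))
  }
  fmt <- if (is.null(dp)) "GT" else "GT:DP"
  body <- apply(gt_str, 1L, paste, collapse = "\t")
  writeLines(paste(vs$sites$contig, vs$sites$pos, ".", vs$sites$ref,
                   vs$sites$alt, ".", "PASS", ".", fmt, body, sep = "\t"),
             con)
  invisible(path)
}

#' Write per-individual calls as a single-sample VCF with DP
#'
#' @param cg a `roh_calls`.
#' @param sites full site table (`contig`, `pos`, `ref`, `alt`) matching
#'   the call set.
#' @param path output file.
#' @param ref optional `roh_reference` for contig header lines.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(cg, sites, path, ref = NULL) {
  vs <- roh_variants(sites, matrix(cg$gt, ncol = 1,
                                   dimnames = list(NULL, cg$individual)))
  write_vcf(vs, path, ref = ref,
            dp = matrix(cg$dp, ncol = 1))
}

#' Read a VCF into a variant set
#'
#' Parses biallelic SNP records via vcfR; genotypes become the 0/1/2/NA
#' dosage coding used throughout the package.
#'
#' @param path VCF file.
#' @return A `roh_variants`.
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_config("read_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  keep <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"], fixed = TRUE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gt_raw <- gsub("|", "/", gt_raw, fixed = TRUE)
  code <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    out
  }
  geno <- apply(gt_raw, 2L, code)
  if (is.null(dim(geno))) geno <- matrix(geno, ncol = ncol(gt_raw))
  colnames(geno) <- colnames(gt_raw)
  sites <- data.frame(contig = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  roh_variants(sites[keep, , drop = FALSE], geno[keep, , drop = FALSE])
}

#' Save / load a generator configuration as JSON
#'
#' Field names mirror [sim_config()] arguments, so a config round-trips.
#'
#' @param cfg a `roh_sim_config`.
#' @param path JSON file path.
#' @return `path` (write) or a `roh_sim_config` (read).
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_config(n_contigs = x$n_contigs, contig_len = x$contig_len,
             het_rate_theta = x$het_rate_theta,
             hom_alt_rate_phi = x$hom_alt_rate_phi,
             roh_length_mix = as.data.frame(x$roh_length_mix),
             target_f_roh_levels = x$target_f_roh_levels,
             min_roh_len = x$min_roh_len, min_roh_gap = x$min_roh_gap,
             f_tol = x$f_tol, seed = x$seed)
}

#' Write truth ROH intervals as one BED file per individual
#'
#' @param pop a `roh_population`.
#' @param dir output directory.
#' @return Character vector of paths, invisibly.
#' @export
write_truth_beds <- function(pop, dir = ".") {
  paths <- vapply(names(pop$truth), function(id) {
    p <- file.path(dir, sprintf("%s.truth.bed", id))
    write_bed(pop$truth[[id]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Write a sweep result as TSV with a JSON settings sidecar
#'
#' One row per (individual, condition) cell; sweep-level settings (group,
#' ranking when present) go to `<path>.json`.
#'
#' @param sw a `roh_sweep` data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sw, path) {
  write.table(as.data.frame(sw), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  side <- list(group = attr(sw, "group"),
               n_rows = nrow(sw),
               columns = names(sw))
  if (!is.null(attr(sw, "ranking")))
    side$ranking <- attr(sw, "ranking")
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
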