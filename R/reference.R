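#' Reference genome container
#'
#' A `roh_reference` holds named contig sequences over the alphabet
#' A/C/G/T/N and is the shared coordinate system for every later stage
#' (haplotype construction, read simulation, fragmentation, ROH calling).
#'
#' @param contigs named character vector, one DNA string per contig.
#' @return An object of class `roh_reference`.
#' @export
roh_reference <- function(contigs) {
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop_config("contig names must be present and unique")
  if (any(nchar(contigs) == 0L))
    stop_config("every contig sequence must be non-empty")
  structure(list(contigs = contigs), class = "roh_reference")
}

#' @export
print.roh_reference <- function(x, ...) {
  lens <- ref_lengths(x)
  cat(sprintf("<roh_reference> %d contig(s), %.3f Mb total\n",
              length(lens), sum(lens) / 1e6))
  for (i in seq_along(lens)) {
    cat(sprintf("  %s  %s bp\n", names(lens)[i],
                format(lens[i], big.mark = ",")))
  }
  invisible(x)
}

#' Contig lengths of a reference
#' @param ref a `roh_reference`.
#' @return Named integer vector of contig lengths.
#' @export
ref_lengths <- function(ref) {
  vapply(ref$contigs, nchar, numeric(1))
}

#' Total reference length in bases
#' @param ref a `roh_reference`.
#' @return Total number of bases across contigs.
#' @export
ref_total_len <- function(ref) sum(ref_lengths(ref))

#' Generate a random reference genome
#'
#' Draws `n_contigs` contigs of `contig_len` i.i.d. uniform A/C/G/T bases
#' (no Ns). Stands in for a gap-free chromosome-level assembly.
#'
#' @param cfg a [sim_config()] (fields `n_contigs`, `contig_len`, `seed`), or
#'   `NULL` to use the explicit arguments.
#' @param n_contigs,contig_len,seed overrides for the config fields.
#' @return A `roh_reference`.
#' @export
make_reference <- function(cfg = NULL, n_contigs = cfg$n_contigs,
                           contig_len = cfg$contig_len, seed = cfg$seed) {
  if (is.null(n_contigs) || is.null(contig_len) ||
      n_contigs < 1L || contig_len < 1e4)
    stop_config("need n_contigs >= 1 and contig_len >= 10 kb")
  bases <- utf8ToInt("ACGT")
  contigs <- with_seed(child_seed(seed, "ref"), {
    vapply(seq_len(n_contigs), function(i) {
      intToUtf8(sample(bases, contig_len, replace = TRUE))
    }, character(1))
  })
  names(contigs) <- sprintf("chr%d", seq_len(n_contigs))
  roh_reference(contigs)
}

# base at 1-based positions of one contig (vectorised, via raw bytes)
ref_base_at <- function(seq, pos) {
  rawToChar(charToRaw(seq)[pos], multiple = TRUE)
}

# replace bases at 1-based positions with single characters
seq_replace_at <- function(seq, pos, repl) {
  r <- charToRaw(seq)
  r[pos] <- charToRaw(paste0(repl, collapse = ""))
  rawToChar(r)
}

#' Write a reference to FASTA
#'
#' 60-column wrapped FASTA via Biostrings.
#'
#' @param ref a `roh_reference`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ref, path) {
  ss <- Biostrings::DNAStringSet(ref$contigs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file into a reference
#' @param path FASTA file path.
#' @return A `roh_reference`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  roh_reference(setNames(as.character(ss), names(ss)))
}
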