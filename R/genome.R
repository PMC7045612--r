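#' Read a (multi-record, possibly soft-masked) FASTA file
#'
#' Sequences are returned as a named character vector over `{A,C,G,T,N}` with
#' lowercase preserved as soft-mask.  Case is kept by reading through
#' [Biostrings::readBStringSet()].
#'
#' @param path FASTA file path.
#' @return named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  validate_genome(out)
}

#' @rdname read_fasta
#' @param genome named character vector of sequences.
#' @param width line-wrap width.
#' @export
write_fasta <- function(genome, path, width = 70) {
  ss <- Biostrings::BStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

validate_genome <- function(genome) {
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("genome sequences must be named by chromosome")
  if (any(nchar(genome) == 0)) stop("empty sequence")
  bad <- grepl("[^ACGTNacgtn]", genome)
  if (any(bad))
    stop("sequence alphabet must be {A,C,G,T,N} (soft-mask lowercase): ",
         paste(names(genome)[bad], collapse = ", "))
  genome
}

#' Chromosome lengths of a genome
#' @param genome named character vector of sequences.
#' @return named integer vector.
#' @export
genome_sizes <- function(genome) setNames(nchar(genome), names(genome))

#' Hard-mask a soft-masked genome
#'
#' Replaces lowercase (soft-masked) bases with `N`, the preparation step for
#' repeat-masked composition and island statistics.
#'
#' @param genome named character vector of sequences.
#' @return genome with masked bases set to `N`.
#' @export
hard_mask <- function(genome) {
  chartr("acgtn", "NNNNN", genome)
}

# Raw-byte view of one chromosome, uppercased; vocabulary for fast counting.
seq_bytes <- function(seq) charToRaw(toupper(seq))

BYTE_A <- charToRaw("A"); BYTE_C <- charToRaw("C")
BYTE_G <- charToRaw("G"); BYTE_T <- charToRaw("T")

# Regions (GRanges) restricted to one chromosome as an IRanges; NULL -> whole.
chrom_regions <- function(regions, chrom, len) {
  if (is.null(regions)) return(IRanges(1L, len))
  r <- regions[as.character(seqnames(regions)) == chrom]
  if (length(r) == 0) return(IRanges())
  ir <- IRanges::reduce(ranges(r))
  if (any(start(ir) < 1) || any(end(ir) > len))
    stop("region out of bounds on ", chrom)
  ir
}
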