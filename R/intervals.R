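#' Construct a validated interval set
#'
#' Builds a [GenomicRanges::GRanges] from chromosome / start / end vectors or
#' validates an existing `GRanges`.  Coordinates are 1-based closed in memory
#' (the Bioconductor convention); BED files are converted at the I/O boundary.
#' Zero-width intervals are rejected, and when `chrom_sizes` is supplied every
#' interval must lie within its declared chromosome.
#'
#' @param chrom chromosome names, or a `GRanges`/`data.frame` holding the set.
#' @param start,end 1-based closed coordinates (ignored when `chrom` is
#'   already a container).
#' @param name optional labels kept in `mcols()$name`.
#' @param chrom_sizes optional named vector of chromosome lengths for bounds
#'   checking.
#' @return a `GRanges` with strand `*`.
#' @export
intervals <- function(chrom, start = NULL, end = NULL, name = NULL,
                      chrom_sizes = NULL) {
  if (is(chrom, "GRanges")) {
    gr <- chrom
  } else if (is.data.frame(chrom)) {
    gr <- GRanges(chrom$chrom, IRanges(chrom$start, chrom$end))
    if (!is.null(chrom$name)) mcols(gr)$name <- chrom$name
  } else {
    gr <- GRanges(chrom, IRanges(start, end))
    if (!is.null(name)) mcols(gr)$name <- name
  }
  GenomicRanges::strand(gr) <- "*"
  if (any(width(gr) < 1))
    stop("zero- or negative-width intervals are not allowed")
  if (!is.null(chrom_sizes)) check_bounds(gr, chrom_sizes)
  gr
}

check_bounds <- function(gr, chrom_sizes) {
  chr <- as.character(seqnames(gr))
  unknown <- setdiff(unique(chr), names(chrom_sizes))
  if (length(unknown))
    stop("chromosome(s) not in chrom_sizes: ", paste(unknown, collapse = ", "))
  if (any(start(gr) < 1) || any(end(gr) > chrom_sizes[chr]))
    stop("interval exceeds declared chromosome bounds")
  invisible(gr)
}

#' Normalize an interval set
#'
#' Sorts per chromosome and merges overlapping or book-ended intervals, so the
#' result is sorted and pairwise non-overlapping.  Equivalent to
#' `merge_within(gr, 0)`.
#'
#' @param gr a `GRanges`.
#' @return normalized `GRanges`.
#' @export
normalize_intervals <- function(gr) merge_within(gr, 0L)

#' Merge intervals separated by at most a gap
#'
#' Consecutive intervals on the same chromosome are merged when the gap
#' between them (bases strictly between the two) is `<= max_gap`; merging is
#' transitive, so chains of nearby intervals collapse into one.  The boundary
#' is inclusive: intervals exactly `max_gap` bases apart merge.  This is the
#' rule used to assemble gene-cluster compartments from lifted-over cluster
#' segments ("within 100 kbp").  Labels of merged members are joined with
#' commas so provenance survives.
#'
#' @param gr a `GRanges`.
#' @param max_gap maximum separating gap in bases (>= 0).
#' @return normalized `GRanges`; `mcols()$name` holds joined labels when the
#'   input carried names.
#' @export
merge_within <- function(gr, max_gap) {
  if (length(max_gap) != 1 || is.na(max_gap) || max_gap < 0)
    stop("max_gap must be a single non-negative number")
  has_names <- !is.null(mcols(gr)$name)
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1,
                               with.revmap = has_names,
                               ignore.strand = TRUE)
  if (has_names) {
    nm <- vapply(red$revmap, function(i) {
      v <- mcols(gr)$name[i]
      paste(v[!is.na(v)], collapse = ",")
    }, character(1))
    mcols(red)$revmap <- NULL
    mcols(red)$name <- nm
  }
  sort(red)
}

#' Keep intervals at least a minimum length
#'
#' The boundary is retained: an interval of exactly `min_len` bases survives
#' (the cluster-compartment rule keeps merged regions of >= 80 kbp).
#'
#' @param gr a `GRanges`.
#' @param min_len minimum width in bases.
#' @return filtered `GRanges`.
#' @export
filter_min_length <- function(gr, min_len) {
  gr[width(gr) >= min_len]
}

#' Complement of an interval set within declared chromosomes
#'
#' Returns, per chromosome in `chrom_sizes`, the gaps between the normalized
#' intervals plus the flanks, so input and output together tile each
#' chromosome exactly once.  Used to build the non-cluster compartment.
#'
#' @param gr a `GRanges` (will be normalized).
#' @param chrom_sizes named vector of chromosome lengths; all listed
#'   chromosomes appear in the result even if absent from `gr`.
#' @return normalized `GRanges` of uncovered bases.
#' @export
interval_complement <- function(gr, chrom_sizes) {
  check_bounds(gr, chrom_sizes)
  whole <- GRanges(names(chrom_sizes), IRanges(1L, as.integer(chrom_sizes)))
  if (length(gr) == 0) return(sort(whole))
  seqlevels(gr) <- union(seqlevels(whole), seqlevels(gr))
  sort(GenomicRanges::setdiff(whole, gr, ignore.strand = TRUE))
}

# Concatenate GRanges built per chromosome (disjoint seqlevels by design)
# without the Seqinfo "no sequence levels in common" warning.
concat_granges <- function(lst) {
  lst <- lst[vapply(lst, length, 0L) > 0]
  if (length(lst) == 0) return(GRanges())
  lv <- unique(unlist(lapply(lst, seqlevels), use.names = FALSE))
  lst <- lapply(lst, function(g) { seqlevels(g) <- lv; g })
  do.call(c, lst)
}

#' Base-level intersection of two interval sets
#'
#' @param a,b `GRanges` objects.
#' @return normalized `GRanges` of bases covered by both.
#' @export
interval_intersect <- function(a, b) {
  lv <- union(seqlevels(a), seqlevels(b))
  seqlevels(a) <- lv
  seqlevels(b) <- lv
  sort(GenomicRanges::intersect(a, b, ignore.strand = TRUE))
}

#' Build gene-cluster compartments from lifted cluster segments
#'
#' Applies the published construction: merge segments within `max_gap` of
#' each other, then retain merged regions of at least `min_len` bases.
#' Defaults are the 100 kbp merge / 80 kbp length rules.
#'
#' @param gr lifted cluster segments (`GRanges`).
#' @param max_gap merge gap in bases.
#' @param min_len minimum retained length in bases.
#' @return cluster compartment `GRanges`.
#' @export
build_clusters <- function(gr, max_gap = 1e5, min_len = 8e4) {
  filter_min_length(merge_within(gr, max_gap), min_len)
}

#' Read / write BED interval files
#'
#' Thin wrappers over [rtracklayer::import()]/[rtracklayer::export()];
#' BED is 0-based half-open on disk and converted to 1-based closed
#' `GRanges` in memory.
#'
#' @param path file path.
#' @return `read_bed()`: a `GRanges` with `name` kept when present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  GenomicRanges::strand(gr) <- "*"
  keep <- intersect("name", colnames(mcols(gr)))
  mcols(gr) <- mcols(gr)[, keep, drop = FALSE]
  gr
}

#' @rdname read_bed
#' @param gr a `GRanges` to write.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a chromosome-sizes file
#'
#' Two-column TSV (chromosome name, length in bases).
#'
#' @param path file path.
#' @return named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, col.names = c("chrom", "size"),
                   colClasses = c("character", "numeric"))
  setNames(df$size, df$chrom)
}

#' Total bases covered by an interval set
#' @param gr a `GRanges`.
#' @return covered base count after normalization.
#' @export
covered_bases <- function(gr) sum(width(normalize_intervals(gr)))
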