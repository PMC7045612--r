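#' Read SNPs from a VCF file
#'
#' Reads a VCF 4.x file (plain or bgzipped) via \pkg{vcfR}, keeps biallelic
#' rows record-wise as they appear, and retains only single-base ref and alt
#' alleles (SNPs).  Multi-allelic ALT fields count once and are represented
#' by their first single-base alternate.  Allele frequency is taken from a
#' configurable INFO key and folded to the minor allele.
#'
#' @param path VCF file path.
#' @param af_key INFO key holding the (alternate) allele frequency
#'   (default `"AF"`); folded so `maf = min(af, 1 - af)`.
#' @return `data.frame` with `chrom`, `pos` (1-based), `ref`, `alt`, `maf`
#'   (`NA` when the key is absent).
#' @export
read_vcf_snps <- function(path, af_key = "AF") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  af <- suppressWarnings(vcfR::extract.info(v, af_key, as.numeric = TRUE))
  if (is.null(af)) af <- rep(NA_real_, nrow(fx))
  alt1 <- vapply(strsplit(fx[, "ALT"], ","), function(a) {
    a1 <- a[nchar(a) == 1 & a %in% c("A", "C", "G", "T")]
    if (length(a1)) a1[1] else NA_character_
  }, character(1))
  df <- data.frame(chrom = fx[, "CHROM"], pos = as.numeric(fx[, "POS"]),
                   ref = fx[, "REF"], alt = alt1,
                   maf = pmin(af, 1 - af))
  df[nchar(df$ref) == 1 & df$ref %in% c("A", "C", "G", "T") &
       !is.na(df$alt), , drop = FALSE]
}

#' Filter variants to common ones by minor-allele frequency
#'
#' Keeps records with `maf >= min_maf` (boundary kept, matching the
#' "MAF >= 0.01" convention for common SNPs).  Records without a MAF are
#' excluded; their number is reported as attribute `n_no_maf`.
#'
#' @param vs variant `data.frame` from [read_vcf_snps()].
#' @param min_maf threshold (default 0.01).
#' @return filtered `data.frame` with attribute `n_no_maf`.
#' @export
filter_common <- function(vs, min_maf = 0.01) {
  no_maf <- is.na(vs$maf)
  out <- vs[!no_maf & vs$maf >= min_maf, , drop = FALSE]
  attr(out, "n_no_maf") <- sum(no_maf)
  out
}

#' SNP density over an interval set
#'
#' Variants per kbp: count of variants whose position lies in `regions`,
#' scaled by the total region length -- or by the non-N (effective) length
#' when a genome is supplied, for the masked-denominator variant.
#'
#' @param vs variant `data.frame`.
#' @param regions `GRanges` (normalized internally).
#' @param genome optional named character vector of sequences; when given the
#'   denominator is the effective (non-N) length of `regions`.
#' @return SNPs/kbp, or `NA` for an empty region set.
#' @export
snp_density <- function(vs, regions, genome = NULL) {
  regions <- normalize_intervals(regions)
  len <- if (is.null(genome)) sum(width(regions)) else {
    ct <- count_bases(genome, regions)
    sum(ct[c("A", "C", "G", "T")])
  }
  if (len == 0) return(NA_real_)
  pos <- GRanges(vs$chrom, IRanges(vs$pos, vs$pos))
  n <- sum(IRanges::overlapsAny(pos, regions))
  n * 1000 / len
}

#' Classify SNPs by CpG dinucleotide context
#'
#' A SNP is "in a CpG" when its reference position is the C or the G of a
#' reference CpG dinucleotide: at 1-based position `p`, either
#' `base[p] == C && base[p+1] == G` or `base[p] == G && base[p-1] == C`.
#' The default covers both positions because deamination mutates the C of
#' either strand (the plus-strand G marks the minus-strand C);
#' `rule = "c_only"` restricts to the C position.  Records whose reference
#' base disagrees with the genome are excluded with a warning and counted.
#' Edge positions evaluate only the existing neighbor.
#'
#' @param vs variant `data.frame`.
#' @param genome named character vector of reference sequences.
#' @param rule `"both"` (default) or `"c_only"`.
#' @return `vs` with added columns `in_cpg` (logical) and `context`
#'   (reference dinucleotide starting at the variant, or ending at it for the
#'   final base); attributes `percent_in_cpg` (100 * in-CpG / classified),
#'   `n_classified`, `n_ref_mismatch`.
#' @export
classify_cpg_snps <- function(vs, genome, rule = c("both", "c_only")) {
  rule <- match.arg(rule)
  unknown <- setdiff(unique(vs$chrom), names(genome))
  if (length(unknown))
    stop("variant chromosome(s) absent from genome: ",
         paste(unknown, collapse = ", "))
  in_cpg <- logical(nrow(vs)); ctx <- character(nrow(vs))
  okref <- logical(nrow(vs))
  for (chrom in unique(vs$chrom)) {
    b <- seq_bytes(genome[[chrom]])
    L <- length(b)
    idx <- which(vs$chrom == chrom)
    p <- vs$pos[idx]
    if (any(p < 1 | p > L)) stop("variant position outside genome on ", chrom)
    base <- rawToChar(b[p], multiple = TRUE)
    okref[idx] <- base == toupper(vs$ref[idx])
    nxt <- ifelse(p < L, rawToChar(b[pmin(p + 1, L)], multiple = TRUE), "")
    prv <- ifelse(p > 1, rawToChar(b[pmax(p - 1, 1)], multiple = TRUE), "")
    is_c <- base == "C" & nxt == "G"
    is_g <- base == "G" & prv == "C"
    in_cpg[idx] <- if (rule == "both") is_c | is_g else is_c
    ctx[idx] <- ifelse(p < L, paste0(base, nxt), paste0(prv, base))
  }
  if (any(!okref))
    warning(sum(!okref), " variant(s) with reference-allele mismatch excluded")
  out <- vs[okref, , drop = FALSE]
  out$in_cpg <- in_cpg[okref]
  out$context <- ctx[okref]
  attr(out, "n_classified") <- nrow(out)
  attr(out, "n_ref_mismatch") <- sum(!okref)
  attr(out, "percent_in_cpg") <-
    if (nrow(out) > 0) 100 * mean(out$in_cpg) else NA_real_
  out
}

#' Write variants as a minimal VCF 4.2 file
#'
#' Used by the synthetic generator; emits `CHROM POS ID REF ALT QUAL FILTER
#' INFO` with `AF=` in INFO.
#'
#' @param vs `data.frame` with `chrom`, `pos`, `ref`, `alt` and optional
#'   `maf`.
#' @param path output path.
#' @param chrom_sizes optional named lengths written as contig headers.
#' @export
write_vcf <- function(vs, path, chrom_sizes = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency">'),
             con)
  if (!is.null(chrom_sizes))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(chrom_sizes),
                       as.integer(chrom_sizes)), con)
  writeLines(paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", sep = "\t"), con)
  info <- if (is.null(vs$maf)) "." else sprintf("AF=%.6f", vs$maf)
  writeLines(paste(vs$chrom, vs$pos, ".", vs$ref, vs$alt, ".", "PASS", info,
                   sep = "\t"), con)
  invisible(path)
}
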