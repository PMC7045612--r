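#' Feature methylation: chromosome versus genome
#'
#' Mean methylation level at covered CpG positions within a feature class,
#' reported for one target chromosome and genome-wide, with their
#' difference.  The track holds levels in `[0, 1]` at CpG positions;
#' positions without data are excluded (CpG-weighted mean).
#'
#' @param track a `score_track` of methylation levels (values in `[0, 1]`).
#' @param features `GRanges` of the feature class (e.g. promoter flanking,
#'   or the "general genomic" complement of all regulatory classes).
#' @param target_chrom chromosome to contrast against the genome-wide mean.
#' @return list with `target_mean`, `genome_mean` (all chromosomes,
#'   target included), `rest_mean` (all chromosomes except the target),
#'   `difference` (`rest_mean - target_mean`; positive = target
#'   hypomethylated) and covered CpG counts.  Means are `NA` when no
#'   covered CpG falls in the corresponding features.  The contrast uses
#'   `rest_mean` rather than `genome_mean` because in a small genome the
#'   target chromosome's own CpGs would otherwise dilute its signal.
#' @export
feature_methylation <- function(track, features, target_chrom) {
  if (any(track$score < 0 | track$score > 1))
    stop("methylation levels must lie in [0, 1]")
  genome_r <- mean_score(track, features)
  on_target <- as.character(seqnames(features)) == target_chrom
  tf <- features[on_target]
  rf <- features[!on_target]
  empty <- list(mean = NA_real_, covered = 0L)
  target_r <- if (length(tf)) mean_score(track, tf) else empty
  rest_r <- if (length(rf)) mean_score(track, rf) else empty
  list(target_mean = target_r$mean,
       genome_mean = genome_r$mean,
       rest_mean = rest_r$mean,
       difference = rest_r$mean - target_r$mean,
       target_covered = target_r$covered,
       genome_covered = genome_r$covered,
       rest_covered = rest_r$covered)
}

#' Mean feature length, chromosome versus genome
#'
#' Arithmetic mean of interval widths (e.g. hypomethylated-region sizes),
#' optionally for one chromosome, with the paired chromosome-vs-genome
#' report.
#'
#' @param features normalized `GRanges` (e.g. HMRs).
#' @param chrom optional chromosome restriction; when given the return value
#'   is a list with `chrom_mean`, `genome_mean` and `difference`
#'   (`chrom_mean - genome_mean`).
#' @return mean length in bp, or the paired list; `NA` when the (subset)
#'   set is empty.
#' @export
mean_feature_length <- function(features, chrom = NULL) {
  if (is.null(chrom)) {
    if (length(features) == 0) return(NA_real_)
    return(mean(width(features)))
  }
  sub <- features[as.character(seqnames(features)) == chrom]
  cm <- if (length(sub)) mean(width(sub)) else NA_real_
  gm <- if (length(features)) mean(width(features)) else NA_real_
  list(chrom_mean = cm, genome_mean = gm, difference = cm - gm)
}
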