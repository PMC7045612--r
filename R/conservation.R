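#' Read a per-base score track (bedGraph or wiggle)
#'
#' Conservation (phyloP-like) or methylation tracks.  Bases not covered by
#' any record carry no data and are excluded from every aggregation
#' (missing-data semantics, not zero-fill).
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format `"auto"`, `"bedGraph"` or `"wig"`.
#' @return a `score_track`: `GRanges` with a numeric `score` column, runs of
#'   equal-valued bases stored as ranges.
#' @export
read_score_track <- function(path, format = c("auto", "bedGraph", "wig")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(wig|wiggle)$", path, ignore.case = TRUE))
      "wig" else "bedGraph"
  }
  gr <- rtracklayer::import(path, format = format)
  score_track(gr)
}

#' @rdname read_score_track
#' @param gr `GRanges` with a `score` metadata column.
#' @export
score_track <- function(gr) {
  if (is.null(gr$score)) stop("track requires a 'score' column")
  if (any(!is.finite(gr$score))) stop("track scores must be finite")
  GenomicRanges::strand(gr) <- "*"
  gr <- sort(gr)
  if (length(gr) > 1 &&
      any(GenomicRanges::countOverlaps(gr, gr) > 1))
    stop("track ranges overlap; one value per base is required")
  gr
}

#' @rdname read_score_track
#' @param track a `score_track`.
#' @export
write_score_track <- function(track, path) {
  rtracklayer::export(track, path, format = "bedGraph")
  invisible(path)
}

#' Mean score over an interval set
#'
#' Arithmetic mean of per-base scores at the bases of `regions` that carry
#' data; uncovered bases are excluded from numerator and denominator
#' (the bwtool convention).  The `accelerated` flag marks a negative mean,
#' the signature of accelerated nucleotide evolution in phyloP-style scores.
#'
#' @param track a `score_track`.
#' @param regions `GRanges`.
#' @return list with `mean`, `covered` (scored base count) and
#'   `accelerated`; `mean` is `NA` and `accelerated` `NA` when no scored
#'   base falls in `regions`.
#' @export
mean_score <- function(track, regions) {
  regions <- normalize_intervals(regions)
  hits <- GenomicRanges::findOverlaps(track, regions, ignore.strand = TRUE)
  if (length(hits) == 0)
    return(list(mean = NA_real_, covered = 0L, accelerated = NA))
  ti <- queryHits(hits); ri <- subjectHits(hits)
  w <- pmin(end(track)[ti], end(regions)[ri]) -
    pmax(start(track)[ti], start(regions)[ri]) + 1
  s <- track$score[ti]
  m <- sum(s * w) / sum(w)
  list(mean = m, covered = as.integer(sum(w)), accelerated = m < 0)
}

#' Score summary per feature class
#'
#' Aggregates a track over several named feature classes (promoters,
#' promoter-flanking, enhancers, CpG islands, whole chromosome, ...).
#' `weight = "base"` (default) averages over scored bases; `"feature"`
#' averages the per-feature means.
#'
#' @param track a `score_track`.
#' @param classes named list of `GRanges`, one per feature class.
#' @param weight `"base"` or `"feature"`.
#' @return `data.frame` with `class`, `mean_score`, `covered`,
#'   `accelerated`.
#' @export
feature_class_summary <- function(track, classes,
                                  weight = c("base", "feature")) {
  weight <- match.arg(weight)
  rows <- lapply(names(classes), function(cl) {
    gr <- classes[[cl]]
    if (weight == "base") {
      r <- mean_score(track, gr)
    } else {
      per <- vapply(seq_along(gr),
                    function(i) mean_score(track, gr[i])$mean, 0)
      cov <- mean_score(track, gr)$covered
      m <- mean(per, na.rm = TRUE)
      r <- list(mean = if (is.nan(m)) NA_real_ else m, covered = cov,
                accelerated = if (is.nan(m)) NA else m < 0)
    }
    data.frame(class = cl, mean_score = r$mean, covered = r$covered,
               accelerated = r$accelerated)
  })
  do.call(rbind, rows)
}

#' Rank chromosomes by mean score
#'
#' Ascending by mean (most diverged / least conserved first); ties broken by
#' name for determinism.
#'
#' @param df `data.frame` with columns `chrom` and `mean_score`.
#' @return `df` reordered.
#' @export
rank_chromosomes <- function(df) {
  if (nrow(df) < 2) stop("need at least two chromosomes to rank")
  df[order(df$mean_score, df$chrom), , drop = FALSE]
}

#' Spearman rank correlation with explicit p-value methods
#'
#' Tie-corrected rho (Pearson correlation of mid-ranks).  The p-value uses
#' the t approximation `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom (two-sided); for `n <= 8`, `p_method = "exact"`
#' enumerates all permutations of one margin instead.
#'
#' @param x,y paired numeric vectors (`n >= 3`), aligned by observation.
#' @param p_method `"t"` (default) or `"exact"`.
#' @return list with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_cor <- function(x, y, p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, method = p_method))
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (p_method == "exact") {
    if (n > 8) stop("exact permutation p-value supported for n <= 8")
    perms <- permutations_of(n)
    obs <- abs(rho)
    cnt <- sum(apply(perms, 1, function(pp) abs(cor(rx, ry[pp])) >= obs - 1e-12))
    p <- cnt / nrow(perms)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p_value = p, n = n, method = p_method)
}

# All permutations of 1..n as a matrix (n <= 8 keeps this small).
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                 sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}
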