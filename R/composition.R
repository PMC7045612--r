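# Base counts (A, C, G, T, N-or-other) over selected regions of a genome.
count_bases <- function(genome, regions = NULL) {
  tot <- c(A = 0, C = 0, G = 0, T = 0, other = 0)
  for (chrom in names(genome)) {
    b <- seq_bytes(genome[[chrom]])
    ir <- chrom_regions(regions, chrom, length(b))
    if (length(ir) == 0) next
    idx <- unlist(lapply(seq_along(ir),
                         function(i) start(ir)[i]:end(ir)[i]), use.names = FALSE)
    bb <- b[idx]
    tot["A"] <- tot["A"] + sum(bb == BYTE_A)
    tot["C"] <- tot["C"] + sum(bb == BYTE_C)
    tot["G"] <- tot["G"] + sum(bb == BYTE_G)
    tot["T"] <- tot["T"] + sum(bb == BYTE_T)
  }
  n_sel <- if (is.null(regions)) sum(nchar(genome)) else {
    sum(vapply(names(genome), function(chrom)
      sum(width(chrom_regions(regions, chrom, nchar(genome[[chrom]])))), 0))
  }
  tot["other"] <- n_sel - sum(tot[c("A", "C", "G", "T")])
  tot
}

#' GC content of a genome or interval subset
#'
#' `(G + C) / (A + C + G + T)` over the selected bases, case-insensitive.
#' `N` (and soft-masked bases hard-masked beforehand, if desired) are excluded
#' from both numerator and denominator.
#'
#' @param genome named character vector of sequences.
#' @param regions optional `GRanges` restricting the calculation.
#' @return GC fraction in `[0,1]`, or `NA` when no unambiguous bases are
#'   selected.
#' @export
gc_content <- function(genome, regions = NULL) {
  ct <- count_bases(genome, regions)
  eff <- sum(ct[c("A", "C", "G", "T")])
  if (eff == 0) return(NA_real_)
  unname((ct["C"] + ct["G"]) / eff)
}

#' Positions of CpG dinucleotides
#'
#' Returns the position of the C of each CpG (case-insensitive).  A CpG
#' straddling a region boundary is counted iff its C lies inside the region.
#'
#' @param genome named character vector of sequences.
#' @param regions optional `GRanges` restriction.
#' @return width-1 `GRanges` at the C of each CpG, 1-based.
#' @export
cpg_positions <- function(genome, regions = NULL) {
  out <- lapply(names(genome), function(chrom) {
    p <- cpg_sites(genome[[chrom]])
    if (!is.null(regions)) {
      ir <- chrom_regions(regions, chrom, nchar(genome[[chrom]]))
      p <- p[IRanges::overlapsAny(IRanges(p, p), ir)]
    }
    if (length(p) == 0) return(GRanges())
    GRanges(chrom, IRanges(p, p))
  })
  concat_granges(out)
}

# 1-based C positions of CpGs in one sequence string.
cpg_sites <- function(seq) {
  b <- seq_bytes(seq)
  L <- length(b)
  if (L < 2) return(integer(0))
  which(b[-L] == BYTE_C & b[-1] == BYTE_G)
}

#' Observed/expected CpG ratio
#'
#' The Gardiner-Garden and Frommer form `N_CpG * L / (N_C * N_G)` with `L`
#' the effective (non-N) length of the selection.  Values well below 1
#' indicate CpG depletion, the genome-wide mammalian norm (~0.2-0.25);
#' CpG islands sit at >= 0.6.
#'
#' @inheritParams gc_content
#' @return ratio `>= 0`, or `NA` when the selection has no C or no G.
#' @export
cpg_obs_exp <- function(genome, regions = NULL) {
  ct <- count_bases(genome, regions)
  eff <- sum(ct[c("A", "C", "G", "T")])
  ncpg <- length(cpg_positions(genome, regions))
  if (ct["C"] == 0 || ct["G"] == 0) return(NA_real_)
  unname(ncpg * eff / (ct["C"] * ct["G"]))
}

#' Per-chromosome composition summary
#'
#' One row per chromosome: total and effective (non-N) length, GC fraction,
#' CpG count, CpG density per kbp of effective sequence, and the
#' observed/expected CpG ratio.  With `regions`, each row summarizes the
#' selected bases on that chromosome only.
#'
#' @inheritParams gc_content
#' @return `data.frame` with columns `chrom`, `length`, `effective_length`,
#'   `gc`, `cpg_count`, `cpg_per_kbp`, `obs_exp`.
#' @export
composition_summary <- function(genome, regions = NULL) {
  rows <- lapply(names(genome), function(chrom) {
    g1 <- genome[chrom]
    ct <- count_bases(g1, regions)
    eff <- sum(ct[c("A", "C", "G", "T")])
    ncpg <- length(cpg_positions(g1, regions))
    data.frame(
      chrom = chrom,
      length = nchar(genome[[chrom]]),
      effective_length = eff,
      gc = if (eff > 0) unname((ct["C"] + ct["G"]) / eff) else NA_real_,
      cpg_count = ncpg,
      cpg_per_kbp = if (eff > 0) ncpg * 1000 / eff else NA_real_,
      obs_exp = if (ct["C"] > 0 && ct["G"] > 0)
        unname(ncpg * eff / (ct["C"] * ct["G"])) else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Gene density in fixed windows, averaged by chromosome
#'
#' Tiles each chromosome into `window`-sized windows (the last may be short);
#' a gene is assigned to the window containing its start.  The per-chromosome
#' mean is taken over all windows, including empty ones.
#'
#' @param genes `GRanges` of gene intervals.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param window window size in bases (default 100 kbp).
#' @return list with `windows` (`data.frame`: `chrom`, `window_start`
#'   (1-based), `count`) and `mean` (named per-chromosome mean count).
#' @export
windowed_gene_density <- function(genes, chrom_sizes, window = 1e5) {
  if (length(window) != 1 || window <= 0) stop("window must be positive")
  if (length(genes)) check_bounds(genes, chrom_sizes)
  win_rows <- lapply(names(chrom_sizes), function(chrom) {
    n_win <- ceiling(chrom_sizes[[chrom]] / window)
    starts <- (seq_len(n_win) - 1) * window + 1
    g <- genes[as.character(seqnames(genes)) == chrom]
    idx <- floor((start(g) - 1) / window) + 1
    counts <- tabulate(idx, nbins = n_win)
    data.frame(chrom = chrom, window_start = starts, count = counts)
  })
  windows <- do.call(rbind, win_rows)
  means <- vapply(split(windows$count, windows$chrom), mean, 0)
  list(windows = windows, mean = means[names(chrom_sizes)])
}
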