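#' Read a GCT / TSV expression matrix
#'
#' GCT 1.2 (two header lines, then `Name`, `Description`, sample columns) or
#' a plain TSV whose first column is the gene id.  Values are TPM.
#'
#' @param path file path.
#' @return numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns.
#' @export
read_gct <- function(path) {
  first <- readLines(path, n = 1)
  skip <- if (startsWith(first, "#1.2")) 2 else 0
  df <- read.delim(path, skip = skip, check.names = FALSE)
  ids <- as.character(df[[1]])
  drop <- 1
  if (ncol(df) > 1 && tolower(colnames(df)[2]) == "description") drop <- 1:2
  m <- as.matrix(df[, -drop, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  m
}

#' Per-gene expression variance across samples
#'
#' Unbiased sample variance (`n - 1` denominator) of each gene's TPM values.
#'
#' @param m genes-by-samples numeric matrix.
#' @return named numeric vector of variances.
#' @export
gene_variance <- function(m) {
  if (ncol(m) < 2) stop("variance requires at least 2 samples")
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

#' Per-chromosome expression summary
#'
#' For each chromosome: the median of per-gene variances, the mean of
#' per-gene mean TPM (genes averaged across samples first, then averaged
#' over the chromosome's genes), and the index of dispersion.  The default
#' index pairs the chromosome's median variance with its mean TPM (the
#' summary-table pipeline: a median-variance table and a mean-TPM table,
#' then their ratio); `index_mode = "per_gene"` instead averages the
#' per-gene variance/mean ratios.
#'
#' @param m genes-by-samples TPM matrix.
#' @param gene_map named character vector: chromosome per gene id.
#' @param min_tpm optional filter: keep genes with mean TPM `>= min_tpm`
#'   (default 0, no filtering).
#' @param index_mode `"median_over_mean"` (default) or `"per_gene"`.
#' @return `data.frame` with `chrom`, `n_genes`, `median_variance`,
#'   `mean_tpm`, `index_of_dispersion`; attribute `n_unassigned` counts
#'   genes without a chromosome.  Chromosomes with no genes are omitted
#'   with a warning.
#' @export
chromosome_expression_summary <- function(m, gene_map, min_tpm = 0,
                                          index_mode = c("median_over_mean",
                                                         "per_gene")) {
  index_mode <- match.arg(index_mode)
  if (any(m < 0)) stop("TPM values must be non-negative")
  chrom <- gene_map[rownames(m)]
  n_unassigned <- sum(is.na(chrom))
  keep <- !is.na(chrom)
  m <- m[keep, , drop = FALSE]; chrom <- chrom[keep]
  gm <- rowMeans(m)
  if (min_tpm > 0) {
    sel <- gm >= min_tpm
    m <- m[sel, , drop = FALSE]; chrom <- chrom[sel]; gm <- gm[sel]
  }
  gv <- gene_variance(m)
  empty <- setdiff(unique(gene_map), unique(chrom))
  if (length(empty))
    warning("chromosome(s) with no genes omitted: ",
            paste(sort(empty), collapse = ", "))
  rows <- lapply(sort(unique(chrom)), function(cc) {
    i <- chrom == cc
    medv <- median(gv[i]); mtpm <- mean(gm[i])
    idx <- if (index_mode == "median_over_mean") {
      if (mtpm > 0) medv / mtpm else NA_real_
    } else {
      r <- gv[i] / gm[i]
      mean(r[is.finite(r)])
    }
    data.frame(chrom = cc, n_genes = sum(i), median_variance = medv,
               mean_tpm = mtpm, index_of_dispersion = idx)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_unassigned") <- n_unassigned
  out
}

#' Average externally supplied per-gene variances by chromosome
#'
#' For cross-species expression-variance tables computed elsewhere: the
#' arithmetic mean of the supplied variances over each chromosome's genes.
#' Genes missing from the map are excluded and counted.
#'
#' @param var_table `data.frame` with columns `gene` and `variance`.
#' @param gene_map named character vector: chromosome per gene id.
#' @return `data.frame` with `chrom`, `n_genes`, `mean_variance`;
#'   attribute `n_unmatched`.
#' @export
average_external_variance <- function(var_table, gene_map) {
  chrom <- gene_map[var_table$gene]
  ok <- !is.na(chrom)
  if (!any(ok)) stop("no genes in the variance table match the gene map")
  sp <- split(var_table$variance[ok], chrom[ok])
  out <- data.frame(chrom = names(sp),
                    n_genes = vapply(sp, length, 0L),
                    mean_variance = vapply(sp, mean, 0))
  rownames(out) <- NULL
  attr(out, "n_unmatched") <- sum(!ok)
  out
}

#' Write an expression matrix in GCT 1.2 format
#' @param m genes-by-samples matrix with rownames.
#' @param path output path.
#' @export
write_gct <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
  df <- data.frame(Name = rownames(m), Description = rownames(m), m,
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
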