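#' Read / write MAF multiple-alignment blocks
#'
#' Plain MAF: `a` lines open a block (optionally with `score=`), `s` lines
#' carry `src start size strand srcSize text`.  `src` is
#' `species.chromosome`; `start` is 0-based on the stated strand.  All gapped
#' texts in a block must have equal length and the ungapped length must
#' equal the declared size.
#'
#' @param path MAF file path.
#' @return list of blocks; each block is a list with `score` and `rows`
#'   (`data.frame`: `src`, `start`, `size`, `strand`, `src_size`, `text`).
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    rows <- cur$rows
    if (length(unique(nchar(rows$text))) > 1)
      stop("ragged alignment block (unequal text lengths) near line ",
           cur$line)
    ungapped <- nchar(gsub("-", "", rows$text))
    if (any(ungapped != rows$size))
      stop("block size disagrees with ungapped text near line ", cur$line)
    blocks[[length(blocks) + 1L]] <<- cur[c("score", "rows")]
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) { flush(); cur <- NULL; next }
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (f[1] == "a") {
      flush()
      sc <- sub("^score=", "", grep("^score=", f, value = TRUE))
      cur <- list(score = if (length(sc)) as.numeric(sc) else NA_real_,
                  rows = data.frame(src = character(), start = numeric(),
                                    size = numeric(), strand = character(),
                                    src_size = numeric(), text = character()),
                  line = i)
    } else if (f[1] == "s") {
      if (is.null(cur)) stop("'s' line outside a block at line ", i)
      if (length(f) != 7) stop("malformed 's' line at line ", i)
      cur$rows <- rbind(cur$rows, data.frame(
        src = f[2], start = as.numeric(f[3]), size = as.numeric(f[4]),
        strand = f[5], src_size = as.numeric(f[6]), text = toupper(f[7])))
    }
  }
  flush()
  blocks
}

#' @rdname read_maf
#' @param blocks list of blocks.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (bl in blocks) {
    writeLines(if (is.na(bl$score)) "a" else paste0("a score=", bl$score), con)
    r <- bl$rows
    writeLines(sprintf("s %s %d %d %s %d %s", r$src, as.integer(r$start),
                       as.integer(r$size), r$strand, as.integer(r$src_size),
                       r$text), con)
    writeLines("", con)
  }
  invisible(path)
}

maf_species <- function(src) sub("\\..*$", "", src)
maf_chrom <- function(src) sub("^[^.]*\\.", "", src)

# Reverse-complement an entire block so that every row reads the opposite
# strand; column correspondence is preserved because all rows flip together.
rc_block <- function(bl) {
  r <- bl$rows
  r$text <- vapply(r$text, function(t) {
    chartr("ACGTN-", "TGCAN-", paste(rev(strsplit(t, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
  r$start <- r$src_size - (r$start + r$size)
  r$strand <- ifelse(r$strand == "+", "-", "+")
  bl$rows <- r
  bl
}

#' Extract pairwise substitutions from alignment blocks
#'
#' A column yields a substitution when both species carry an unambiguous
#' base (`A/C/G/T`) and the bases differ; gap or `N` columns are skipped.
#' Coordinates are reported 1-based on the forward strand of `species_a`
#' (blocks whose `species_a` row is on the minus strand are
#' reverse-complemented whole).  Each substitution carries a CpG-context
#' flag: with `cpg_rule = "either"` (default) the site is flagged when it is
#' the C or the G of a CpG in at least one of the two species, evaluated on
#' each species' own gap-stripped sequence within the block (a deamination
#' event destroys the CpG in one species, so a single-species rule
#' systematically undercounts); `"reference"` uses `species_a` only.  Sites
#' at the edge of a species' block sequence evaluate only the existing
#' neighbor.
#'
#' @param blocks list of blocks from [read_maf()].
#' @param species_a,species_b species names (the `src` prefix before `.`).
#' @param cpg_rule `"either"` or `"reference"`.
#' @return `data.frame` with `chrom`, `pos`, `ref`, `alt`, `in_cpg`,
#'   `context_a`, `context_b`; attribute `n_blocks_skipped` counts blocks
#'   lacking one of the species.
#' @export
extract_substitutions <- function(blocks, species_a, species_b,
                                  cpg_rule = c("either", "reference")) {
  cpg_rule <- match.arg(cpg_rule)
  skipped <- 0L
  out <- list()
  for (bl in blocks) {
    sp <- maf_species(bl$rows$src)
    ia <- which(sp == species_a); ib <- which(sp == species_b)
    if (length(ia) != 1 || length(ib) != 1) { skipped <- skipped + 1L; next }
    if (bl$rows$strand[ia] == "-") {
      bl <- rc_block(bl)
    }
    ra <- bl$rows[ia, ]; rb <- bl$rows[ib, ]
    ta <- strsplit(ra$text, "")[[1]]; tb <- strsplit(rb$text, "")[[1]]
    ngap_a <- ta != "-"
    base_ok <- function(x) x %in% c("A", "C", "G", "T")
    is_sub <- base_ok(ta) & base_ok(tb) & ta != tb
    if (!any(is_sub)) next
    # position of each column in species_a forward coordinates (1-based)
    pos_a <- ra$start + cumsum(ngap_a)     # valid where ngap_a
    ctx <- function(txt) {
      t <- strsplit(txt, "")[[1]]
      keep <- t != "-"
      strip <- t[keep]
      k <- cumsum(keep)                    # stripped index per column
      prev <- ifelse(k > 1, strip[pmax(k - 1, 1)], "")
      nxt <- ifelse(k < length(strip), strip[pmin(k + 1, length(strip))], "")
      cpg <- (t == "C" & nxt == "G") | (t == "G" & prev == "C")
      dinuc <- ifelse(nxt != "", paste0(t, nxt), paste0(prev, t))
      list(cpg = cpg & keep, dinuc = ifelse(keep, dinuc, ""))
    }
    ca <- ctx(ra$text); cb <- ctx(rb$text)
    j <- which(is_sub)
    in_cpg <- if (cpg_rule == "either") ca$cpg[j] | cb$cpg[j] else ca$cpg[j]
    out[[length(out) + 1L]] <- data.frame(
      chrom = maf_chrom(ra$src), pos = pos_a[j], ref = ta[j], alt = tb[j],
      in_cpg = in_cpg, context_a = ca$dinuc[j], context_b = cb$dinuc[j])
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = numeric(), ref = character(),
               alt = character(), in_cpg = logical(),
               context_a = character(), context_b = character())
  rownames(res) <- NULL
  attr(res, "n_blocks_skipped") <- skipped
  res
}

#' Percent of substitutions in CpG context
#'
#' `100 * in-CpG / classified`, per chromosome and overall, optionally
#' restricted to an interval compartment.
#'
#' @param subs `data.frame` from [extract_substitutions()].
#' @param regions optional `GRanges` restriction.
#' @return list with `by_chrom` (`data.frame`: `chrom`, `n`, `n_cpg`,
#'   `percent`) and `overall`; `overall` is `NA` when nothing is classified.
#' @export
percent_in_cpg <- function(subs, regions = NULL) {
  if (!is.null(regions) && nrow(subs) > 0) {
    pos <- GRanges(subs$chrom, IRanges(subs$pos, subs$pos))
    subs <- subs[IRanges::overlapsAny(pos, normalize_intervals(regions)), ,
                 drop = FALSE]
  }
  if (nrow(subs) == 0)
    return(list(by_chrom = data.frame(chrom = character(), n = integer(),
                                      n_cpg = integer(), percent = numeric()),
                overall = NA_real_))
  sp <- split(subs$in_cpg, subs$chrom)
  by_chrom <- data.frame(chrom = names(sp),
                         n = vapply(sp, length, 0L),
                         n_cpg = vapply(sp, sum, 0L))
  by_chrom$percent <- 100 * by_chrom$n_cpg / by_chrom$n
  rownames(by_chrom) <- NULL
  list(by_chrom = by_chrom, overall = 100 * mean(subs$in_cpg))
}
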