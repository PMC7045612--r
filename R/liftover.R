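#' Read a UCSC chain file
#'
#' Parses the plain-text chain format: a header line
#' `chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart
#' qEnd id` followed by alignment-block triples `size dt dq` (the final line
#' a bare `size`).  Coordinates are 0-based half-open; negative-strand query
#' coordinates are on the reversed strand, as in the format definition.
#' Internal consistency (block sizes plus gaps equal the stated spans) is
#' verified; violations raise an error naming the offending line.
#'
#' @param path chain file path.
#' @return list of chains; each a list with `score`, `t_name`, `t_size`,
#'   `t_start`, `t_end`, `q_name`, `q_size`, `q_strand`, `q_start`, `q_end`,
#'   `id`, and `blocks` (`data.frame` with `size`, `dt`, `dq`).
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (f[1] != "chain" || length(f) < 12)
      stop("malformed chain header at line ", i)
    if (f[5] != "+")
      stop("target strand must be '+' (line ", i, ")")
    hdr <- list(score = as.numeric(f[2]),
                t_name = f[3], t_size = as.numeric(f[4]),
                t_start = as.numeric(f[6]), t_end = as.numeric(f[7]),
                q_name = f[8], q_size = as.numeric(f[9]), q_strand = f[10],
                q_start = as.numeric(f[11]), q_end = as.numeric(f[12]),
                id = if (length(f) >= 13) f[13] else NA_character_)
    i <- i + 1L
    sizes <- numeric(0); dts <- numeric(0); dqs <- numeric(0)
    repeat {
      if (i > length(lines)) stop("unexpected end of chain file at line ", i)
      b <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      if (length(b) == 1 && b != "") {
        sizes <- c(sizes, as.numeric(b)); dts <- c(dts, 0); dqs <- c(dqs, 0)
        i <- i + 1L
        break
      } else if (length(b) == 3) {
        sizes <- c(sizes, as.numeric(b[1]))
        dts <- c(dts, as.numeric(b[2])); dqs <- c(dqs, as.numeric(b[3]))
        i <- i + 1L
      } else stop("malformed chain block at line ", i)
    }
    if (any(is.na(sizes)) || any(sizes <= 0))
      stop("non-positive block size in chain ending at line ", i - 1)
    if (sum(sizes) + sum(dts) != hdr$t_end - hdr$t_start ||
        sum(sizes) + sum(dqs) != hdr$q_end - hdr$q_start)
      stop("inconsistent chain spans in chain ending at line ", i - 1)
    hdr$blocks <- data.frame(size = sizes, dt = dts, dq = dqs)
    chains[[length(chains) + 1L]] <- hdr
  }
  chains
}

#' @rdname read_chain
#' @param chains list of chains as returned by `read_chain()`.
#' @export
write_chain <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    writeLines(paste("chain", format(ch$score, scientific = FALSE),
                     ch$t_name, ch$t_size, "+", ch$t_start, ch$t_end,
                     ch$q_name, ch$q_size, ch$q_strand, ch$q_start, ch$q_end,
                     if (is.na(ch$id)) "1" else ch$id), con)
    n <- nrow(ch$blocks)
    if (n > 1)
      writeLines(paste(ch$blocks$size[-n], ch$blocks$dt[-n],
                       ch$blocks$dq[-n]), con)
    writeLines(c(as.character(ch$blocks$size[n]), ""), con)
  }
  invisible(path)
}

# Per-chain mapping of one 0-based half-open source interval.
# Returns forward-strand target pieces (0-based half-open) and mapped bases.
map_through_chain <- function(ch, s0, e0) {
  ts <- ch$t_start; qs <- ch$q_start
  pieces <- list()
  mapped <- 0
  for (k in seq_len(nrow(ch$blocks))) {
    size <- ch$blocks$size[k]
    os <- max(s0, ts); oe <- min(e0, ts + size)
    if (oe > os) {
      q0 <- qs + (os - ts); q1 <- qs + (oe - ts)
      if (ch$q_strand == "-") { tmp <- q0; q0 <- ch$q_size - q1; q1 <- ch$q_size - tmp }
      pieces[[length(pieces) + 1L]] <- c(q0, q1)
      mapped <- mapped + (oe - os)
    }
    ts <- ts + size + ch$blocks$dt[k]
    qs <- qs + size + ch$blocks$dq[k]
  }
  list(pieces = pieces, mapped = mapped)
}

#' Lift intervals through chain alignments
#'
#' Maps each interval's bases through the aligned blocks of overlapping
#' chains.  A chain's mapping is acceptable when the fraction of interval
#' bases falling in aligned blocks is at least `min_match` (the UCSC
#' `minMatch` meaning).  With `allow_multiple = FALSE` only the best-scoring
#' acceptable chain is used, and a mapping broken into several target pieces
#' is reported as `split` with no targets (mirroring `liftOver` without
#' `-multiple`); with `allow_multiple = TRUE` all acceptable chains
#' contribute and split pieces are all reported.  Negative-strand targets are
#' reported in forward coordinates of the target assembly.
#'
#' @param gr source intervals (`GRanges`, 1-based closed).
#' @param chains list of chains from [read_chain()].
#' @param min_match minimum mapped-base fraction in `(0, 1]`.
#' @param allow_multiple allow multiple mappings / split pieces.
#' @return object of class `lift_result`: list with `summary`
#'   (`data.frame`: source coordinates, `status` in
#'   `lifted/partially_deleted/split/unmapped`, `fraction`, `n_targets`) and
#'   `targets` (`GRangesList` parallel to the input, forward target
#'   coordinates, 1-based closed).
#' @export
lift_intervals <- function(gr, chains, min_match = 0.1,
                           allow_multiple = FALSE) {
  if (min_match <= 0 || min_match > 1) stop("min_match must be in (0, 1]")
  status <- character(length(gr)); frac <- numeric(length(gr))
  targets <- vector("list", length(gr))
  chrs <- as.character(seqnames(gr))
  ord_score <- order(-vapply(chains, `[[`, 0, "score"))
  for (i in seq_along(gr)) {
    s0 <- start(gr)[i] - 1; e0 <- end(gr)[i]
    best <- NULL; all_pieces <- list(); best_frac <- 0
    for (j in ord_score) {
      ch <- chains[[j]]
      if (ch$t_name != chrs[i] || ch$t_end <= s0 || ch$t_start >= e0) next
      m <- map_through_chain(ch, s0, e0)
      f <- m$mapped / (e0 - s0)
      if (f < min_match || m$mapped == 0) next
      if (allow_multiple) {
        all_pieces <- c(all_pieces, lapply(m$pieces, function(p)
          list(q_name = ch$q_name, p = p)))
        best_frac <- max(best_frac, f)
      } else if (is.null(best)) {
        best <- list(ch = ch, m = m, f = f)   # chains visited best-score first
      }
    }
    if (allow_multiple) {
      if (length(all_pieces) == 0) {
        status[i] <- "unmapped"; frac[i] <- 0; targets[[i]] <- GRanges()
      } else {
        g <- concat_granges(lapply(all_pieces, function(x)
          GRanges(x$q_name, IRanges(x$p[1] + 1, x$p[2]))))
        targets[[i]] <- GenomicRanges::reduce(sort(g))
        status[i] <- "lifted"; frac[i] <- best_frac
      }
    } else if (is.null(best)) {
      status[i] <- "unmapped"; frac[i] <- 0; targets[[i]] <- GRanges()
    } else {
      g <- do.call(c, lapply(best$m$pieces, function(p)
        GRanges(best$ch$q_name, IRanges(p[1] + 1, p[2]))))
      g <- GenomicRanges::reduce(sort(g))
      frac[i] <- best$f
      if (length(g) > 1) {
        status[i] <- "split"; targets[[i]] <- GRanges()
      } else {
        status[i] <- if (best$f == 1) "lifted" else "partially_deleted"
        targets[[i]] <- g
      }
    }
  }
  res <- list(
    summary = data.frame(chrom = chrs, start = start(gr), end = end(gr),
                         status = status, fraction = frac,
                         n_targets = vapply(targets, length, 0L)),
    targets = GRangesList(targets))
  class(res) <- "lift_result"
  res
}

#' @export
print.lift_result <- function(x, ...) {
  cat("lift_result:", nrow(x$summary), "source interval(s);",
      sum(x$summary$status != "unmapped"), "mapped\n")
  print(head(x$summary, 10))
  invisible(x)
}

#' Reciprocal liftOver orthology filter
#'
#' Lifts intervals A to B (allowing multiple mappings, as needed for
#' repeat-rich regions), lifts every resulting segment back B to A, and
#' retains a source interval only if some round trip returns to its original
#' coordinates.  By default the round trip must be coordinate-exact; with
#' `mode = "overlap"` a reciprocal overlap of at least `min_overlap` of the
#' longer interval suffices.
#'
#' @param gr source intervals (`GRanges`).
#' @param chains_ab,chains_ba chain lists for the two directions.
#' @param min_match `minMatch` fraction used in both directions.
#' @param mode `"exact"` (default) or `"overlap"`.
#' @param min_overlap reciprocal overlap fraction for `mode = "overlap"`.
#' @return the retained subset of `gr`.
#' @export
reciprocal_filter <- function(gr, chains_ab, chains_ba, min_match = 0.1,
                              mode = c("exact", "overlap"),
                              min_overlap = 0.95) {
  mode <- match.arg(mode)
  if (length(gr) == 0) return(gr)
  fwd <- lift_intervals(gr, chains_ab, min_match, allow_multiple = TRUE)
  keep <- logical(length(gr))
  for (i in seq_along(gr)) {
    tg <- fwd$targets[[i]]
    if (length(tg) == 0) next
    back <- lift_intervals(tg, chains_ba, min_match, allow_multiple = FALSE)
    for (j in seq_along(tg)) {
      bg <- back$targets[[j]]
      if (length(bg) != 1) next
      same_chr <- as.character(seqnames(bg)) == as.character(seqnames(gr[i]))
      if (!same_chr) next
      if (mode == "exact") {
        if (start(bg) == start(gr[i]) && end(bg) == end(gr[i])) keep[i] <- TRUE
      } else {
        ov <- min(end(bg), end(gr[i])) - max(start(bg), start(gr[i])) + 1
        if (ov / max(width(bg), width(gr[i])) >= min_overlap) keep[i] <- TRUE
      }
      if (keep[i]) break
    }
  }
  gr[keep]
}

# Swap the two sides of a plus-strand chain (used by the synthetic generator
# to derive the return-direction chain file).
invert_chain <- function(ch) {
  if (ch$q_strand != "+") stop("invert_chain supports '+' strand chains only")
  list(score = ch$score,
       t_name = ch$q_name, t_size = ch$q_size,
       t_start = ch$q_start, t_end = ch$q_end,
       q_name = ch$t_name, q_size = ch$t_size, q_strand = "+",
       q_start = ch$t_start, q_end = ch$t_end, id = ch$id,
       blocks = data.frame(size = ch$blocks$size, dt = ch$blocks$dq,
                           dq = ch$blocks$dt))
}
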