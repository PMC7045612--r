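# Brute-force oracles and small fixture builders shared across tests.

library(GenomicRanges)

gr_ <- function(chrom, start, end) intervals(chrom, start, end)

# O(n^2) transitive-closure merge oracle over a chrom/start/end data.frame.
oracle_merge <- function(df, max_gap) {
  repeat {
    merged <- FALSE
    i <- 1
    while (i <= nrow(df) && !merged) {
      j <- i + 1
      while (j <= nrow(df)) {
        if (df$chrom[i] == df$chrom[j]) {
          gap <- max(df$start[i], df$start[j]) - min(df$end[i], df$end[j]) - 1
          if (gap <= max_gap) {
            df$start[i] <- min(df$start[i], df$start[j])
            df$end[i] <- max(df$end[i], df$end[j])
            df <- df[-j, , drop = FALSE]
            merged <- TRUE
            break
          }
        }
        j <- j + 1
      }
      i <- i + 1
    }
    if (!merged) break
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Chromosome-name/start sorted view (GRanges sorts by seqlevel order of
# appearance, which is irrelevant to the comparisons made here).
gr_to_df <- function(gr) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr), end = end(gr))
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Per-chromosome coverage bitmaps.
bitmap <- function(gr, sizes) {
  out <- lapply(names(sizes), function(chrom) {
    v <- logical(sizes[[chrom]])
    sub <- gr[as.character(seqnames(gr)) == chrom]
    for (i in seq_along(sub)) v[start(sub)[i]:end(sub)[i]] <- TRUE
    v
  })
  setNames(out, names(sizes))
}

random_intervals <- function(sizes, n) {
  chrom <- sample(names(sizes), n, replace = TRUE)
  s <- vapply(chrom, function(cc) sample.int(sizes[[cc]], 1), 0L)
  w <- sample.int(30, n, replace = TRUE)
  e <- pmin(s + w - 1L, sizes[chrom])
  intervals(chrom, s, e)
}

# Character-level composition oracle for one sequence.
oracle_comp <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  nA <- sum(ch == "A"); nC <- sum(ch == "C")
  nG <- sum(ch == "G"); nT <- sum(ch == "T")
  eff <- nA + nC + nG + nT
  L <- length(ch)
  ncpg <- if (L < 2) 0L else sum(ch[-L] == "C" & ch[-1] == "G")
  list(gc = if (eff > 0) (nC + nG) / eff else NA_real_,
       ncpg = ncpg, eff = eff,
       obs_exp = if (nC > 0 && nG > 0) ncpg * eff / (nC * nG) else NA_real_)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T", "N", "a", "c",
                                       "g", "t")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcomp <- function(seq) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# Per-base mean-score oracle: expand track to vectors, average region bases.
oracle_mean_score <- function(track, regions, sizes) {
  vals <- lapply(sizes, function(L) rep(NA_real_, L))
  for (i in seq_along(track)) {
    cc <- as.character(seqnames(track))[i]
    vals[[cc]][start(track)[i]:end(track)[i]] <- track$score[i]
  }
  bm <- bitmap(normalize_intervals(regions), sizes)
  sel <- unlist(lapply(names(sizes), function(cc) vals[[cc]][bm[[cc]]]))
  sel <- sel[!is.na(sel)]
  if (length(sel) == 0) NA_real_ else mean(sel)
}

# Walk one chain block list to map a single 0-based source base; returns the
# 0-based forward target position or NA.
oracle_map_base <- function(ch, p0) {
  ts <- ch$t_start; qs <- ch$q_start
  for (k in seq_len(nrow(ch$blocks))) {
    size <- ch$blocks$size[k]
    if (p0 >= ts && p0 < ts + size) {
      q <- qs + (p0 - ts)
      if (ch$q_strand == "-") q <- ch$q_size - q - 1
      return(q)
    }
    ts <- ts + size + ch$blocks$dt[k]
    qs <- qs + size + ch$blocks$dq[k]
  }
  NA_real_
}

# A small deterministic genome used by several suites.
tiny_genome <- function() {
  c(chrA = "ACGTACGGCCGCGTANNNACGTTTTTACGCGCATG",
    chrB = "TTTTCGCGTACGATCGAAATTTCCGG")
}
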