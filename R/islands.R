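# GC fraction and obs/exp of one subsequence (byte vector view).
region_stats <- function(b, s, e) {
  bb <- b[s:e]
  nC <- sum(bb == BYTE_C); nG <- sum(bb == BYTE_G)
  nA <- sum(bb == BYTE_A); nT <- sum(bb == BYTE_T)
  eff <- nA + nC + nG + nT
  ncpg <- sum(bb[-length(bb)] == BYTE_C & bb[-1] == BYTE_G)
  # C at the region's last base with a G just beyond still counts
  if (e < length(b) && b[e] == BYTE_C && b[e + 1] == BYTE_G) ncpg <- ncpg + 1
  gc <- if (eff > 0) (nC + nG) / eff else NA_real_
  oe <- if (nC > 0 && nG > 0) ncpg * eff / (nC * nG) else NA_real_
  list(gc = gc, obs_exp = oe, eff = eff)
}

#' Call CpG islands with a sliding-window scheme
#'
#' Classic Gardiner-Garden style caller: 200-bp windows shifted 1 bp are
#' scored for GC fraction and observed/expected CpG ratio; windows passing
#' both thresholds are merged when overlapping, candidates are split at `N`
#' runs longer than `max_n_run`, then trimmed one base at a time and
#' re-tested until the reported region itself satisfies all thresholds.
#' Regions shorter than `min_len` after trimming are dropped.
#'
#' @param genome named character vector of sequences (hard-mask first for the
#'   repeat-masked variant, see [hard_mask()]).
#' @param min_len minimum island length (default 200 bp).
#' @param min_gc minimum GC fraction (default 0.50).
#' @param min_obs_exp minimum observed/expected CpG ratio (default 0.60).
#' @param max_n_run longest run of `N` tolerated inside an island
#'   (default 0: islands contain no `N`).
#' @return `GRanges` of islands with `gc` and `obs_exp` metadata columns.
#' @export
find_cpg_islands <- function(genome, min_len = 200, min_gc = 0.50,
                             min_obs_exp = 0.60, max_n_run = 0) {
  if (min_len <= 0 || min_gc <= 0 || min_obs_exp <= 0)
    stop("thresholds must be positive")
  w <- 200L
  out <- lapply(names(genome), function(chrom) {
    b <- seq_bytes(genome[[chrom]])
    L <- length(b)
    if (L < max(w, min_len)) return(GRanges())
    isC <- as.numeric(b == BYTE_C); isG <- as.numeric(b == BYTE_G)
    isN <- as.numeric(!(b == BYTE_A | b == BYTE_C | b == BYTE_G | b == BYTE_T))
    iscpg <- c(isC[-L] * isG[-1], 0)
    win <- function(x) { cs <- c(0, cumsum(x)); cs[(w + 1):(L + 1)] - cs[1:(L - w + 1)] }
    nC <- win(isC); nG <- win(isG); nN <- win(isN); nCpG <- win(iscpg)
    eff <- w - nN
    gc <- ifelse(eff > 0, (nC + nG) / eff, NA)
    oe <- ifelse(nC > 0 & nG > 0, nCpG * eff / (nC * nG), NA)
    pass <- !is.na(gc) & !is.na(oe) & gc >= min_gc & oe >= min_obs_exp &
      nN <= max_n_run
    if (!any(pass)) return(GRanges())
    s <- which(pass)
    cand <- IRanges::reduce(IRanges(s, s + w - 1L))
    cand <- split_at_n_runs(cand, isN, max_n_run)
    ivs <- trim_candidates(b, cand, min_len, min_gc, min_obs_exp)
    if (length(ivs) == 0) return(GRanges())
    st <- lapply(seq_along(ivs), function(i)
      region_stats(b, start(ivs)[i], end(ivs)[i]))
    GRanges(chrom, ivs,
            gc = vapply(st, `[[`, 0, "gc"),
            obs_exp = vapply(st, `[[`, 0, "obs_exp"))
  })
  concat_granges(out)
}

# Break candidate ranges wherever an N run longer than max_n_run occurs.
split_at_n_runs <- function(cand, isN, max_n_run) {
  r <- rle(isN)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  long_n <- which(r$values == 1 & r$lengths > max_n_run)
  if (length(long_n) == 0) return(cand)
  bad <- IRanges(starts[long_n], ends[long_n])
  IRanges::setdiff(cand, bad)
}

# Shrink each candidate until it passes both thresholds (or gets too short).
trim_candidates <- function(b, cand, min_len, min_gc, min_obs_exp) {
  keep <- list()
  ok <- function(st) !is.na(st$gc) && !is.na(st$obs_exp) &&
    st$gc >= min_gc && st$obs_exp >= min_obs_exp
  for (i in seq_along(cand)) {
    s <- start(cand)[i]; e <- end(cand)[i]
    repeat {
      if (e - s + 1 < min_len) break
      st <- region_stats(b, s, e)
      if (ok(st)) { keep[[length(keep) + 1]] <- c(s, e); break }
      # drop the edge base that is not G/C first; ties trim the right end
      if (b[s] != BYTE_C && b[s] != BYTE_G) s <- s + 1 else e <- e - 1
    }
  }
  if (length(keep) == 0) return(IRanges())
  m <- do.call(rbind, keep)
  IRanges(m[, 1], m[, 2])
}

#' CpG island bases per kbp
#'
#' Total island bases scaled per kbp of effective sequence.  For the
#' repeat-masked variant, hard-mask the genome (lowercase to `N`) before
#' calling islands and use that genome's effective length.
#'
#' @param islands `GRanges` of non-overlapping islands.
#' @param effective_length denominator base count (non-N bases of the
#'   sequence the islands were called on).
#' @return island bases / kbp.
#' @export
island_density <- function(islands, effective_length) {
  if (effective_length <= 0) stop("effective_length must be positive")
  sum(width(islands)) * 1000 / effective_length
}
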