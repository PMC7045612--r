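# ---- Markov sequence model ---------------------------------------------
#
# A first-order chain over {A,C,G,T} with a single CpG-depletion knob: rows
# start from the stationary marginals p_A = p_T = (1-g)/2, p_C = p_G = g/2,
# and the C row's transition to G is scaled by a factor s, then the row is
# renormalized.  Renormalization perturbs the stationary distribution, so
# both the input GC and the scale are calibrated against the analytic
# stationary distribution until the chain's expected GC and obs/exp hit
# their targets.

markov_params <- function(gc, obs_exp, tol = 1e-8, max_iter = 200) {
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  if (obs_exp < 0) stop("obs_exp must be >= 0")
  if (gc == 0) {
    P <- matrix(0, 4, 4, dimnames = list(DNA4, DNA4))
    P[, "A"] <- 0.5; P[, "T"] <- 0.5
    return(list(trans = P, init = c(A = .5, C = 0, G = 0, T = .5)))
  }
  u <- gc; s <- max(obs_exp, 1e-9)
  for (iter in seq_len(max_iter)) {
    P <- base_trans(u, s)
    pi <- stationary(P)
    gc_a <- pi["C"] + pi["G"]
    r_a <- if (pi["G"] > 0) P["C", "G"] / pi["G"] else 0
    if (abs(gc_a - gc) < tol && abs(r_a - obs_exp) < tol)
      return(list(trans = P, init = pi))
    u <- min(max(u * gc / gc_a, 1e-9), 1 - 1e-9)
    if (r_a > 0) s <- s * obs_exp / r_a
    if (s > 1e8)
      stop("obs_exp target infeasible for this GC (C row cannot renormalize)")
  }
  if (abs(r_a - obs_exp) > 0.01)
    stop("Markov calibration failed to reach the obs/exp target")
  list(trans = P, init = pi)
}

DNA4 <- c("A", "C", "G", "T")

base_trans <- function(u, s) {
  p <- c(A = (1 - u) / 2, C = u / 2, G = u / 2, T = (1 - u) / 2)
  P <- matrix(rep(p, each = 4), 4, 4, dimnames = list(DNA4, DNA4))
  P["C", "G"] <- s * p["G"]
  P["C", ] <- P["C", ] / sum(P["C", ])
  P
}

stationary <- function(P) {
  A <- rbind(t(P) - diag(4), rep(1, 4))
  b <- c(rep(0, 4), 1)
  pi <- qr.solve(A, b)
  pi[pi < 0] <- 0
  setNames(pi / sum(pi), DNA4)
}

#' Simulate a chromosome sequence with target GC and CpG obs/exp
#'
#' First-order Markov chain calibrated (via its analytic stationary
#' distribution) so the expected GC fraction equals `gc` and the expected
#' observed/expected CpG ratio equals `obs_exp`.  Randomness comes from R's
#' RNG: call `set.seed()` first for reproducibility.  A requested
#' `softmask_frac` lowercases random intervals to emulate repeat
#' soft-masking.
#'
#' @param length sequence length in bases.
#' @param gc target GC fraction in `[0, 1]`.
#' @param obs_exp target CpG observed/expected ratio (`>= 0`).
#' @param softmask_frac approximate fraction of bases soft-masked
#'   (default 0).
#' @param mask_len mean masked-interval length (default 500 bp).
#' @return a character scalar sequence.
#' @export
generate_sequence <- function(length, gc, obs_exp, softmask_frac = 0,
                              mask_len = 500) {
  mp <- markov_params(gc, obs_exp)
  s <- markov_chain_seq(as.integer(length), mp$trans, mp$init)
  if (softmask_frac > 0) {
    n_iv <- max(1L, round(length * softmask_frac / mask_len))
    starts <- sort(sample.int(max(1L, length - mask_len), n_iv, replace = TRUE))
    ends <- pmin(length, starts + mask_len - 1L)
    b <- charToRaw(s)
    idx <- unique(unlist(lapply(seq_along(starts), function(i)
      starts[i]:ends[i]), use.names = FALSE))
    b[idx] <- as.raw(bitwOr(as.integer(b[idx]), 0x20L))
    s <- rawToChar(b)
  }
  s
}

# ---- variants -----------------------------------------------------------

#' Plant SNPs with a controlled CpG fraction
#'
#' Places exactly `round(density * length / 1000)` SNPs per chromosome at
#' distinct positions; the stated fraction sits on the C or G of a reference
#' CpG (deamination-style alternates `C>T` / `G>A`), the rest at positions
#' outside any CpG (uniform alternates).  MAFs are drawn uniform(0.001, 0.5).
#' The returned table is its own truth table (`in_cpg` column).
#'
#' @param genome named character vector of sequences.
#' @param density SNPs per kbp, recycled or named per chromosome.
#' @param cpg_fraction fraction of SNPs planted in CpG context, recycled or
#'   named per chromosome.
#' @return `data.frame` with `chrom`, `pos`, `ref`, `alt`, `maf`, `in_cpg`.
#' @export
generate_variants <- function(genome, density, cpg_fraction = 0.2) {
  chroms <- names(genome)
  dens <- recycle_per_chrom(density, chroms)
  cfr <- recycle_per_chrom(cpg_fraction, chroms)
  out <- lapply(chroms, function(chrom) {
    b <- seq_bytes(genome[[chrom]])
    L <- length(b)
    n <- round(dens[[chrom]] * L / 1000)
    if (n == 0) return(NULL)
    cpos <- cpg_sites(genome[[chrom]])
    pool_cpg <- sort(unique(c(cpos, cpos + 1L)))
    acgt <- which(b == BYTE_A | b == BYTE_C | b == BYTE_G | b == BYTE_T)
    pool_non <- setdiff(acgt, pool_cpg)
    n_cpg <- round(n * cfr[[chrom]])
    if (n_cpg > length(pool_cpg) || (n - n_cpg) > length(pool_non))
      stop("requested SNP counts infeasible on ", chrom)
    p_cpg <- sample(pool_cpg, n_cpg)
    p_non <- sample(pool_non, n - n_cpg)
    pos <- c(p_cpg, p_non)
    ref <- rawToChar(b[pos], multiple = TRUE)
    alt <- character(length(pos))
    alt[seq_len(n_cpg)] <- ifelse(ref[seq_len(n_cpg)] == "C", "T", "A")
    if (n - n_cpg > 0) {
      alt[(n_cpg + 1):n] <- vapply(ref[(n_cpg + 1):n], function(r)
        sample(setdiff(DNA4, r), 1), character(1))
    }
    df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                     maf = runif(n, 0.001, 0.5),
                     in_cpg = c(rep(TRUE, n_cpg), rep(FALSE, n - n_cpg)))
    df[order(df$pos), ]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

recycle_per_chrom <- function(x, chroms) {
  if (!is.null(names(x))) {
    miss <- setdiff(chroms, names(x))
    if (length(miss)) stop("missing per-chromosome value for: ",
                           paste(miss, collapse = ", "))
    return(as.list(x[chroms]))
  }
  setNames(as.list(rep_len(x, length(chroms))), chroms)
}

# ---- alignment partner --------------------------------------------------

#' Simulate a diverged alignment partner and MAF blocks
#'
#' Copies each chromosome and substitutes each site independently with
#' probability `rate`, multiplied by `kappa` when the site is the C or G of
#' a CpG in the source (CpG hypermutability; those sites take
#' deamination-style `C>T` / `G>A` alternates, others a uniform alternate).
#' Two-species MAF blocks of at most `block_size` columns are emitted; block
#' boundaries are nudged so no source CpG is split across blocks, which
#' keeps block-local CpG context identical to genome-wide context.
#'
#' @param genome named character vector of source sequences.
#' @param rate per-site substitution probability (non-CpG).
#' @param kappa CpG rate multiplier (`>= 1`); `rate * kappa` must be `<= 1`.
#' @param block_size maximum alignment-block width (default 10 kbp).
#' @param species names of the two species (source first).
#' @return list with `blocks` (MAF blocks, see [read_maf()]), `partner`
#'   (the diverged genome) and `truth` (`data.frame`: `chrom`, `pos`,
#'   `ref`, `alt`, `in_cpg`).
#' @export
generate_alignment_partner <- function(genome, rate = 0.005, kappa = 10,
                                       block_size = 10000,
                                       species = c("spA", "spB")) {
  if (rate * kappa > 1) stop("rate * kappa must be <= 1")
  blocks <- list(); truth <- list()
  partner <- genome
  for (chrom in names(genome)) {
    src <- toupper(genome[[chrom]])
    b <- charToRaw(src)
    L <- length(b)
    cpos <- cpg_sites(src)
    in_cpg <- logical(L)
    in_cpg[c(cpos, cpos + 1L)] <- TRUE
    base_ok <- b == BYTE_A | b == BYTE_C | b == BYTE_G | b == BYTE_T
    p <- ifelse(in_cpg, rate * kappa, rate)
    hit <- which(runif(L) < p & base_ok)
    ref <- rawToChar(b[hit], multiple = TRUE)
    alt <- character(length(hit))
    is_cpg_hit <- in_cpg[hit]
    alt[is_cpg_hit] <- ifelse(ref[is_cpg_hit] == "C", "T",
                              ifelse(ref[is_cpg_hit] == "G", "A",
                                     NA_character_))
    if (any(!is_cpg_hit))
      alt[!is_cpg_hit] <- vapply(ref[!is_cpg_hit], function(r)
        sample(setdiff(DNA4, r), 1), character(1))
    prt <- b
    prt[hit] <- charToRaw(paste(alt, collapse = ""))
    partner[[chrom]] <- rawToChar(prt)
    if (length(hit))
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = chrom, pos = hit, ref = ref, alt = alt, in_cpg = is_cpg_hit)
    # block boundaries, shifted right so a CpG never straddles a cut
    s <- 1L
    while (s <= L) {
      e <- min(L, s + block_size - 1L)
      if (e < L && b[e] == BYTE_C && b[e + 1L] == BYTE_G) e <- e + 1L
      blocks[[length(blocks) + 1L]] <- list(
        score = 0,
        rows = data.frame(
          src = paste(species, chrom, sep = "."),
          start = s - 1L, size = e - s + 1L, strand = "+",
          src_size = L,
          text = c(substr(src, s, e), rawToChar(prt[s:e]))))
      s <- e + 1L
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), in_cpg = logical())
  rownames(truth) <- NULL
  list(blocks = blocks, partner = partner, truth = truth)
}

# ---- planted features, tracks, methylation, expression ------------------

# n non-overlapping intervals of width w on [1, len], avoiding `forbidden`.
plant_intervals <- function(chrom, len, n, w, forbidden = NULL) {
  taken <- if (is.null(forbidden)) IRanges() else
    ranges(forbidden[as.character(seqnames(forbidden)) == chrom])
  starts <- integer(0)
  tries <- 0
  while (length(starts) < n && tries < 200 * n) {
    tries <- tries + 1
    st <- sample.int(len - w, 1)
    cand <- IRanges(st, st + w - 1)
    if (!any(IRanges::overlapsAny(cand, taken))) {
      taken <- c(taken, cand)
      starts <- c(starts, st)
    }
  }
  if (length(starts) < n) stop("could not place ", n, " intervals on ", chrom)
  GRanges(chrom, IRanges(sort(starts), width = w))
}

#' Plant regulatory feature classes on a genome
#'
#' Non-overlapping promoter, promoter-flanking, enhancer and background
#' intervals per chromosome, the substrate for synthetic score and
#' methylation tracks.
#'
#' @param chrom_sizes named chromosome lengths.
#' @param n_per_class named counts per class (defaults: 8 promoters, 8
#'   promoter-flanking, 12 enhancers, 10 background).
#' @param widths named widths per class in bp.
#' @return named list of `GRanges`, one per class.
#' @export
plant_features <- function(chrom_sizes,
                           n_per_class = c(promoter = 8,
                                           promoter_flanking = 8,
                                           enhancer = 12, background = 10),
                           widths = c(promoter = 500,
                                      promoter_flanking = 1000,
                                      enhancer = 600, background = 1000)) {
  classes <- names(n_per_class)
  out <- setNames(lapply(classes, function(cl) list()), classes)
  for (chrom in names(chrom_sizes)) {
    placed <- list()
    for (cl in classes) {
      g <- plant_intervals(chrom, chrom_sizes[[chrom]], n_per_class[[cl]],
                           widths[[cl]],
                           forbidden = if (length(placed))
                             concat_granges(placed) else NULL)
      placed <- c(placed, list(g))
      out[[cl]] <- c(out[[cl]], list(g))
    }
  }
  lapply(out, concat_granges)
}

#' Simulate a conservation-style score track with planted class means
#'
#' Per-base scores over the planted features: class mean plus Gaussian
#' noise.  Negative class means emulate accelerated nucleotide evolution.
#'
#' @param features named list of `GRanges` (see [plant_features()]).
#' @param class_means named numeric means per class.
#' @param noise_sd Gaussian noise standard deviation (default 0.2).
#' @return list with `track` (a `score_track`) and `truth` (`data.frame`:
#'   `class`, `mean`).
#' @export
generate_score_track <- function(features, class_means, noise_sd = 0.2) {
  grs <- lapply(names(features), function(cl) {
    g <- features[[cl]]
    pos <- unlist(lapply(seq_along(g), function(i)
      start(g)[i]:end(g)[i]), use.names = FALSE)
    chrom <- rep(as.character(seqnames(g)), width(g))
    GRanges(chrom, IRanges(pos, pos),
            score = class_means[[cl]] + rnorm(length(pos), 0, noise_sd))
  })
  track <- score_track(concat_granges(grs))
  list(track = track,
       truth = data.frame(class = names(features),
                          mean = unname(class_means[names(features)])))
}

#' Simulate a methylation track with a hypomethylated target chromosome
#'
#' Clipped-Gaussian methylation levels at every CpG (C position): one mean
#' genome-wide, a lower mean on the target chromosome.
#'
#' @param genome named character vector of sequences.
#' @param target_chrom the hypomethylated chromosome.
#' @param genome_mean,target_mean compartment means (defaults 0.75 / 0.66).
#' @param sd Gaussian spread before clipping to `[0, 1]` (default 0.1).
#' @return list with `track` and `truth` (the two means).
#' @export
generate_methylation <- function(genome, target_chrom, genome_mean = 0.75,
                                 target_mean = 0.66, sd = 0.1) {
  grs <- lapply(names(genome), function(chrom) {
    p <- cpg_sites(genome[[chrom]])
    if (length(p) == 0) return(GRanges())
    mu <- if (chrom == target_chrom) target_mean else genome_mean
    v <- pmin(1, pmax(0, rnorm(length(p), mu, sd)))
    GRanges(chrom, IRanges(p, p), score = v)
  })
  list(track = score_track(concat_granges(grs)),
       truth = data.frame(compartment = c("genome", target_chrom),
                          mean = c(genome_mean, target_mean)))
}

#' Simulate a TPM expression matrix with per-chromosome dispersion
#'
#' Log-normal TPM per gene; one chromosome can get its log-scale standard
#' deviation multiplied (doubled by default for the target), which drives
#' its index of dispersion up.
#'
#' @param chroms chromosome names.
#' @param n_genes genes per chromosome (default 120).
#' @param n_samples samples (default 30).
#' @param mean_log,sd_mean_log distribution of per-gene log-mean expression.
#' @param base_sdlog per-gene log-scale noise SD (default 0.5).
#' @param sigma_multiplier named per-chromosome multipliers (others 1).
#' @return list with `matrix` (genes x samples), `gene_map` (named
#'   chromosome per gene) and `truth` (the multipliers).
#' @export
generate_expression <- function(chroms, n_genes = 120, n_samples = 30,
                                mean_log = log(10), sd_mean_log = 1,
                                base_sdlog = 0.5,
                                sigma_multiplier = c()) {
  mult <- setNames(rep(1, length(chroms)), chroms)
  mult[names(sigma_multiplier)] <- sigma_multiplier
  rows <- list(); ids <- character(0); map <- character(0)
  for (chrom in chroms) {
    mu <- rnorm(n_genes, mean_log, sd_mean_log)
    m <- t(vapply(mu, function(m1)
      exp(rnorm(n_samples, m1, base_sdlog * mult[[chrom]])),
      numeric(n_samples)))
    rows[[chrom]] <- m
    id <- sprintf("g_%s_%03d", chrom, seq_len(n_genes))
    ids <- c(ids, id)
    map <- c(map, setNames(rep(chrom, n_genes), id))
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- ids
  colnames(mat) <- sprintf("s%02d", seq_len(n_samples))
  list(matrix = mat, gene_map = map,
       truth = data.frame(chrom = chroms, sigma_multiplier = unname(mult)))
}

# ---- chain pair ---------------------------------------------------------

#' Simulate a rearranged partner assembly with chain files both ways
#'
#' Builds assembly B from A by deleting the given intervals and (optionally)
#' shuffling the order of the surviving segments per chromosome, then emits
#' consistent chains A->B and B->A (one chain per surviving segment).  The
#' truth table records each segment's coordinates in both assemblies;
#' intervals fully inside one surviving segment round-trip exactly under
#' [reciprocal_filter()], intervals inside deletions are unmapped.
#'
#' @param genome named character vector (assembly A).
#' @param deletions `GRanges` of A intervals absent from B (may overlap
#'   nothing; normalized internally).
#' @param shuffle permute surviving segment order per chromosome.
#' @param b_suffix appended to chromosome names in assembly B.
#' @return list with `genome_b`, `chains_ab`, `chains_ba`, `truth`
#'   (`data.frame`: `chrom`, `a_start`, `a_end` 1-based closed, `b_chrom`,
#'   `b_start`, `b_end`).
#' @export
generate_chain_pair <- function(genome, deletions = GRanges(),
                                shuffle = FALSE, b_suffix = "") {
  sizes <- genome_sizes(genome)
  if (length(deletions)) {
    check_bounds(deletions, sizes)
    deletions <- normalize_intervals(deletions)
  }
  genome_b <- list(); chains_ab <- list(); truth <- list()
  for (chrom in names(genome)) {
    len <- sizes[[chrom]]
    del_c <- deletions[as.character(seqnames(deletions)) == chrom]
    keep <- if (length(del_c))
      GenomicRanges::setdiff(GRanges(chrom, IRanges(1, len)), del_c) else
      GRanges(chrom, IRanges(1, len))
    segs <- data.frame(start = start(keep), end = end(keep))
    if (nrow(segs) == 0) next
    ord <- if (shuffle && nrow(segs) > 1) sample(nrow(segs)) else
      seq_len(nrow(segs))
    bchrom <- paste0(chrom, b_suffix)
    bseq <- paste(vapply(ord, function(i)
      substr(genome[[chrom]], segs$start[i], segs$end[i]), character(1)),
      collapse = "")
    genome_b[[bchrom]] <- bseq
    blen <- nchar(bseq)
    off <- 0
    for (i in ord) {
      w <- segs$end[i] - segs$start[i] + 1
      chains_ab[[length(chains_ab) + 1L]] <- list(
        score = w, t_name = chrom, t_size = len,
        t_start = segs$start[i] - 1, t_end = segs$end[i],
        q_name = bchrom, q_size = blen, q_strand = "+",
        q_start = off, q_end = off + w,
        id = as.character(length(chains_ab) + 1L),
        blocks = data.frame(size = w, dt = 0, dq = 0))
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = chrom, a_start = segs$start[i], a_end = segs$end[i],
        b_chrom = bchrom, b_start = off + 1, b_end = off + w)
      off <- off + w
    }
  }
  list(genome_b = unlist(genome_b),
       chains_ab = chains_ab,
       chains_ba = lapply(chains_ab, invert_chain),
       truth = do.call(rbind, truth))
}

# ---- full study fixture -------------------------------------------------

#' The default multi-species study conditions
#'
#' Twelve species, five chromosomes each (`chr1`..`chr4` plus a
#' `chr19`-like outlier), lengths 0.5-1 Mbp.  The outlier carries GC 0.48
#' and CpG obs/exp 0.34 against a background of 0.41 / 0.25, SNP density
#' 5/kbp against 3/kbp, and a higher CpG-SNP fraction (0.25 vs 0.18) --
#' the compositional contrast the analysis is designed to detect.
#'
#' @param n_species number of species (default 12).
#' @param n_background background chromosomes per species (default 4).
#' @param min_len,max_len chromosome length range in bp.
#' @return `data.frame` with one row per species x chromosome: `species`,
#'   `chrom`, `gc`, `obs_exp`, `snp_per_kbp`, `cpg_snp_fraction`,
#'   `is_target` (lengths are drawn at simulation time).
#' @export
default_study_spec <- function(n_species = 12, n_background = 4,
                               min_len = 5e5, max_len = 1e6) {
  rows <- list()
  for (s in seq_len(n_species)) {
    species <- sprintf("sp%02d", s)
    chroms <- c(paste0("chr", seq_len(n_background)), "chr19")
    is_t <- chroms == "chr19"
    rows[[s]] <- data.frame(
      species = species, chrom = chroms,
      gc = ifelse(is_t, 0.48, 0.41),
      obs_exp = ifelse(is_t, 0.34, 0.25),
      snp_per_kbp = ifelse(is_t, 5, 3),
      cpg_snp_fraction = ifelse(is_t, 0.25, 0.18),
      is_target = is_t)
  }
  out <- do.call(rbind, rows)
  attr(out, "min_len") <- min_len
  attr(out, "max_len") <- max_len
  out
}

#' Simulate the full study fixture set
#'
#' Generates, deterministically for a seed, the multi-species genomes and
#' variant sets of the study conditions, and for the first species a "deep"
#' fixture layer: planted regulatory features, a conservation-style score
#' track (enhancer and promoter-flanking means negative), a methylation
#' track with a hypomethylated target chromosome, an expression matrix with
#' a doubled-sigma target chromosome, an alignment partner with CpG-biased
#' substitutions, and a rearranged assembly with reciprocal chain files.
#' When `dir` is given, every artifact is also written in its standard
#' plain-text format with a `.truth.tsv` table beside it.
#'
#' @param seed integer seed; identical seed and spec give byte-identical
#'   output.
#' @param spec study specification from [default_study_spec()].
#' @param dir optional output directory.
#' @param softmask_frac soft-masked fraction of each chromosome.
#' @param class_means planted score-track class means.
#' @param noise_sd score-track noise SD.
#' @param kappa CpG substitution-rate multiplier for the alignment partner.
#' @param sub_rate base substitution rate for the alignment partner.
#' @return list with `spec`, `genomes` (list per species), `variants`
#'   (list per species, truth-table form) and `deep` (first-species layer:
#'   `features`, `score`, `methylation`, `expression`, `alignment`,
#'   `chains`).
#' @export
simulate_study <- function(seed, spec = default_study_spec(), dir = NULL,
                           softmask_frac = 0.05,
                           class_means = c(promoter = 0.2,
                                           promoter_flanking = -0.0064,
                                           enhancer = -0.026,
                                           background = 0.05),
                           noise_sd = 0.2, kappa = 10, sub_rate = 0.005) {
  set.seed(seed)
  min_len <- attr(spec, "min_len") %||% 5e5
  max_len <- attr(spec, "max_len") %||% 1e6
  spec$length <- round(runif(nrow(spec), min_len, max_len))
  genomes <- list(); variants <- list()
  for (species in unique(spec$species)) {
    sp <- spec[spec$species == species, ]
    g <- setNames(vector("list", nrow(sp)), sp$chrom)
    for (i in seq_len(nrow(sp)))
      g[[sp$chrom[i]]] <- generate_sequence(sp$length[i], sp$gc[i],
                                            sp$obs_exp[i], softmask_frac)
    g <- unlist(g)
    genomes[[species]] <- g
    variants[[species]] <- generate_variants(
      g, setNames(sp$snp_per_kbp, sp$chrom),
      setNames(sp$cpg_snp_fraction, sp$chrom))
  }
  sp1 <- unique(spec$species)[1]
  g1 <- genomes[[sp1]]
  target <- spec$chrom[spec$species == sp1 & spec$is_target][1]
  features <- plant_features(genome_sizes(g1))
  score <- generate_score_track(features, class_means, noise_sd)
  meth <- generate_methylation(g1, target)
  expr <- generate_expression(names(g1),
                              sigma_multiplier = setNames(2, target))
  aln <- generate_alignment_partner(g1, rate = sub_rate, kappa = kappa,
                                    species = c(sp1, "partner"))
  del_w <- min(5e4, floor(nchar(g1[[1]]) * 0.1))
  del <- GRanges(names(g1)[1],
                 IRanges(round(nchar(g1[[1]]) * 0.4), width = del_w))
  chains <- generate_chain_pair(g1, deletions = del, shuffle = TRUE,
                                b_suffix = "")
  out <- list(spec = spec, genomes = genomes, variants = variants,
              deep = list(species = sp1, target = target,
                          features = features, score = score,
                          methylation = meth, expression = expr,
                          alignment = aln, chains = chains))
  if (!is.null(dir)) write_study(out, dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write every artifact of a simulated study in plain-text formats, each with
# its truth table beside it (<prefix>.truth.tsv).
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtruth <- function(df, prefix)
    write.table(df, file.path(dir, paste0(prefix, ".truth.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  for (species in names(study$genomes)) {
    g <- study$genomes[[species]]
    write_fasta(g, file.path(dir, paste0(species, ".fa")))
    sizes <- genome_sizes(g)
    write.table(data.frame(names(sizes), sizes),
                file.path(dir, paste0(species, ".chrom.sizes")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    v <- study$variants[[species]]
    write_vcf(v, file.path(dir, paste0(species, ".vcf")), sizes)
    wtruth(v, paste0(species, ".vcf"))
  }
  d <- study$deep
  for (cl in names(d$features))
    write_bed(d$features[[cl]], file.path(dir, paste0("features_", cl, ".bed")))
  write_score_track(d$score$track, file.path(dir, "conservation.bedGraph"))
  wtruth(d$score$truth, "conservation.bedGraph")
  write_score_track(d$methylation$track, file.path(dir, "methylation.bedGraph"))
  wtruth(d$methylation$truth, "methylation.bedGraph")
  write_gct(d$expression$matrix, file.path(dir, "expression.gct"))
  write.table(data.frame(gene = names(d$expression$gene_map),
                         chrom = unname(d$expression$gene_map)),
              file.path(dir, "gene_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  wtruth(d$expression$truth, "expression.gct")
  write_maf(d$alignment$blocks, file.path(dir, "alignment.maf"))
  wtruth(d$alignment$truth, "alignment.maf")
  write_fasta(d$chains$genome_b, file.path(dir, "assembly_b.fa"))
  write_chain(d$chains$chains_ab, file.path(dir, "a_to_b.chain"))
  write_chain(d$chains$chains_ba, file.path(dir, "b_to_a.chain"))
  wtruth(d$chains$truth, "a_to_b.chain")
  invisible(dir)
}
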