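#' Run the per-chromosome reporting pipeline
#'
#' Orchestrates the analysis stages over one genome and writes the
#' per-chromosome report that mirrors the study's supplementary-table
#' layout.  `config` is a named list (or the path of a YAML file holding
#' one) with entries:
#'
#' * `genome`: FASTA path (required).
#' * `stages`: subset of `composition`, `islands`, `snps`, `conservation`,
#'   `substitutions`, `expression`, `methylation` (default: all whose
#'   inputs are present).
#' * `vcf`, `af_key`, `min_maf`: variant inputs.
#' * `conservation`, `features` (named list of BED paths): score inputs.
#' * `maf`, `species` (length-2): alignment inputs.
#' * `expression`, `gene_map`: expression inputs.
#' * `methylation`, `target_chrom`: methylation inputs.
#' * `clusters_bed`: optional compartment; when present, compartment rows
#'   (cluster / non-cluster) are added to the report.
#'
#' Input file hashes, the config hash and the recorded seed are logged so
#' two runs with identical inputs are identical.  Missing input files are
#' reported before any computation.
#'
#' @param config list or YAML file path.
#' @param out_dir output directory for `report.tsv` (per chromosome),
#'   `feature_classes.tsv` (conservation by feature class) and
#'   `compartments.tsv` (when clusters are given).  Undefined values are
#'   written as `NA`.
#' @param quiet suppress progress logging.
#' @return invisibly, a list with `report`, `feature_classes`,
#'   `compartments` data frames.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  log <- function(...) if (!quiet) message("[chromcomp] ", ...)
  paths <- c(genome = config$genome, vcf = config$vcf,
             conservation = config$conservation, maf = config$maf,
             expression = config$expression, gene_map = config$gene_map,
             methylation = config$methylation,
             clusters = config$clusters_bed,
             unlist(config$features))
  paths <- paths[!vapply(paths, is.null, TRUE)]
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  if (is.null(config$genome)) stop("config$genome is required")
  all_stages <- c("composition", "islands", "snps", "conservation",
                  "substitutions", "expression", "methylation")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (p in paths) log("input ", p, " md5=", unname(tools::md5sum(p)))
  if (!is.null(config$seed)) log("seed ", config$seed)

  genome <- read_fasta(config$genome)
  sizes <- genome_sizes(genome)
  report <- data.frame(chrom = names(genome), length = unname(sizes))
  feature_classes <- NULL
  compartments <- NULL
  clusters <- if (!is.null(config$clusters_bed))
    read_bed(config$clusters_bed) else NULL

  if ("composition" %in% stages) {
    log("stage composition")
    cs <- composition_summary(genome)
    report <- merge(report, cs[, c("chrom", "effective_length", "gc",
                                   "cpg_count", "cpg_per_kbp", "obs_exp")],
                    by = "chrom", sort = FALSE)
  }
  if ("islands" %in% stages) {
    log("stage islands")
    isl <- find_cpg_islands(genome)
    masked <- hard_mask(genome)
    isl_m <- find_cpg_islands(masked)
    per <- function(islands, g) vapply(names(g), function(chrom) {
      ct <- count_bases(g[chrom])
      eff <- sum(ct[c("A", "C", "G", "T")])
      sub <- islands[as.character(seqnames(islands)) == chrom]
      if (eff > 0) sum(width(sub)) * 1000 / eff else NA_real_
    }, 0)
    report$island_bases_per_kbp <- per(isl, genome)[report$chrom]
    report$island_bases_per_kbp_masked <- per(isl_m, masked)[report$chrom]
  }
  if ("snps" %in% stages && !is.null(config$vcf)) {
    log("stage snps")
    vs <- read_vcf_snps(config$vcf, af_key = config$af_key %||% "AF")
    common <- filter_common(vs, config$min_maf %||% 0.01)
    dens <- function(v) vapply(report$chrom, function(chrom)
      snp_density(v[v$chrom == chrom, ],
                  GRanges(chrom, IRanges(1, sizes[[chrom]]))), 0)
    report$snps_per_kbp_all <- dens(vs)
    report$snps_per_kbp_common <- dens(common)
    cls <- classify_cpg_snps(vs, genome)
    pc <- vapply(split(cls$in_cpg, cls$chrom),
                 function(x) 100 * mean(x), 0)
    report$cpg_snp_percent <- unname(pc[report$chrom])
    if (!is.null(clusters)) {
      noncl <- interval_complement(clusters, sizes)
      compartments <- rbind(
        data.frame(compartment = "cluster",
                   snps_per_kbp = snp_density(vs, clusters),
                   gc = gc_content(genome, clusters)),
        data.frame(compartment = "non_cluster",
                   snps_per_kbp = snp_density(vs, noncl),
                   gc = gc_content(genome, noncl)))
    }
  }
  if ("conservation" %in% stages && !is.null(config$conservation)) {
    log("stage conservation")
    track <- read_score_track(config$conservation)
    whole <- lapply(report$chrom, function(chrom)
      GRanges(chrom, IRanges(1, sizes[[chrom]])))
    ms <- vapply(whole, function(g) mean_score(track, g)$mean, 0)
    report$mean_conservation <- ms
    if (!is.null(config$features)) {
      classes <- lapply(config$features, read_bed)
      feature_classes <- feature_class_summary(track, classes)
    }
  }
  if ("substitutions" %in% stages && !is.null(config$maf)) {
    log("stage substitutions")
    blocks <- read_maf(config$maf)
    sp <- config$species
    if (is.null(sp) || length(sp) != 2)
      stop("config$species must name the two aligned species")
    subs <- extract_substitutions(blocks, sp[1], sp[2])
    pc <- percent_in_cpg(subs)
    report$substitution_cpg_percent <-
      pc$by_chrom$percent[match(report$chrom, pc$by_chrom$chrom)]
  }
  if ("expression" %in% stages && !is.null(config$expression)) {
    log("stage expression")
    m <- read_gct(config$expression)
    gm <- read.delim(config$gene_map)
    gmap <- setNames(gm$chrom, gm$gene)
    es <- chromosome_expression_summary(m, gmap)
    report <- merge(report, es[, c("chrom", "median_variance", "mean_tpm",
                                   "index_of_dispersion")],
                    by = "chrom", all.x = TRUE, sort = FALSE)
  }
  if ("methylation" %in% stages && !is.null(config$methylation)) {
    log("stage methylation")
    track <- read_score_track(config$methylation)
    ms <- vapply(report$chrom, function(chrom)
      mean_score(track, GRanges(chrom, IRanges(1, sizes[[chrom]])))$mean, 0)
    report$methylation_mean <- ms
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) if (!is.null(df))
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
  wr(report, "report.tsv")
  wr(feature_classes, "feature_classes.tsv")
  wr(compartments, "compartments.tsv")
  log("report written to ", file.path(out_dir, "report.tsv"))
  invisible(list(report = report, feature_classes = feature_classes,
                 compartments = compartments))
}

#' Rank chromosomes by a report column
#'
#' Descending by the chosen metric, deterministic tie-break by chromosome
#' name; tied values are flagged.
#'
#' @param report per-chromosome `data.frame` (from [run_pipeline()] or
#'   [composition_summary()]).
#' @param column metric column name.
#' @return `report` reordered with a `rank` column (ties share the minimum
#'   rank) and a logical `tied` column.
#' @export
rank_table <- function(report, column) {
  if (!column %in% colnames(report))
    stop("unknown column '", column, "'; valid columns: ",
         paste(setdiff(colnames(report), "chrom"), collapse = ", "))
  v <- report[[column]]
  out <- report[order(-v, report$chrom), , drop = FALSE]
  out$rank <- rank(-out[[column]], ties.method = "min")
  out$tied <- duplicated(out[[column]]) | duplicated(out[[column]],
                                                     fromLast = TRUE)
  rownames(out) <- NULL
  out
}
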