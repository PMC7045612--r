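write_small_study <- function(dir, seed = 21) {
  spec <- default_study_spec(n_species = 1, n_background = 2,
                             min_len = 1.5e5, max_len = 2e5)
  simulate_study(seed, spec, dir = dir)
}

report_config <- function(dir) {
  sp1 <- "sp01"
  list(genome = file.path(dir, paste0(sp1, ".fa")),
       vcf = file.path(dir, paste0(sp1, ".vcf")),
       conservation = file.path(dir, "conservation.bedGraph"),
       features = list(
         promoter = file.path(dir, "features_promoter.bed"),
         enhancer = file.path(dir, "features_enhancer.bed")),
       maf = file.path(dir, "alignment.maf"),
       species = c(sp1, "partner"),
       expression = file.path(dir, "expression.gct"),
       gene_map = file.path(dir, "gene_map.tsv"),
       methylation = file.path(dir, "methylation.bedGraph"),
       seed = 21)
}

test_that("run_pipeline produces a complete, deterministic report", {
  dir <- tempfile("study")
  out1 <- tempfile("out")
  out2 <- tempfile("out")
  on.exit(unlink(c(dir, out1, out2), recursive = TRUE))
  st <- write_small_study(dir)
  cfg <- report_config(dir)
  r1 <- run_pipeline(cfg, out1, quiet = TRUE)
  r2 <- run_pipeline(cfg, out2, quiet = TRUE)
  expect_identical(readLines(file.path(out1, "report.tsv")),
                   readLines(file.path(out2, "report.tsv")))
  rep <- r1$report
  expect_setequal(rep$chrom, names(st$genomes$sp01))
  needed <- c("gc", "obs_exp", "cpg_per_kbp", "island_bases_per_kbp",
              "snps_per_kbp_all", "snps_per_kbp_common", "cpg_snp_percent",
              "mean_conservation", "substitution_cpg_percent",
              "median_variance", "mean_tpm", "index_of_dispersion",
              "methylation_mean")
  expect_true(all(needed %in% colnames(rep)))
  expect_false(any(is.na(rep$gc)))
  expect_s3_class(r1$feature_classes, "data.frame")
  # the chr19-like chromosome shows its planted contrasts in one run
  t19 <- rep[rep$chrom == "chr19", ]
  bg <- rep[rep$chrom != "chr19", ]
  expect_gt(t19$gc, max(bg$gc))
  expect_gt(t19$snps_per_kbp_all, max(bg$snps_per_kbp_all))
  expect_lt(t19$methylation_mean, min(bg$methylation_mean))
})

test_that("missing inputs are reported before any computation", {
  dir <- tempfile("study")
  on.exit(unlink(dir, recursive = TRUE))
  write_small_study(dir)
  cfg <- report_config(dir)
  cfg$vcf <- file.path(dir, "nope.vcf")
  expect_error(run_pipeline(cfg, tempfile(), quiet = TRUE),
               "missing input file.*nope\\.vcf")
  cfg2 <- report_config(dir)
  cfg2$stages <- c("composition", "flux_capacitor")
  expect_error(run_pipeline(cfg2, tempfile(), quiet = TRUE),
               "unknown stage")
})

test_that("a YAML config file drives the same pipeline", {
  dir <- tempfile("study")
  out <- tempfile("out")
  on.exit(unlink(c(dir, out), recursive = TRUE))
  write_small_study(dir)
  cfg <- report_config(dir)
  cfg$stages <- c("composition")
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  r <- run_pipeline(yml, out, quiet = TRUE)
  expect_true("gc" %in% colnames(r$report))
  expect_false("snps_per_kbp_all" %in% colnames(r$report))
})

test_that("rank_table ranks descending with ties flagged", {
  df <- data.frame(chrom = c("a", "b", "c"), gc = c(0.4, 0.5, 0.4))
  rt <- rank_table(df, "gc")
  expect_equal(rt$chrom, c("b", "a", "c"))
  expect_equal(rt$rank, c(1L, 2L, 2L))
  expect_equal(rt$tied, c(FALSE, TRUE, TRUE))
  expect_error(rank_table(df, "nope"), "valid columns: gc")
})
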