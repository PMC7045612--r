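small_spec <- function() default_study_spec(n_species = 2, n_background = 2,
                                            min_len = 1.5e5, max_len = 2e5)

test_that("identical seeds give byte-identical studies, different ones not", {
  a <- simulate_study(11, small_spec())
  b <- simulate_study(11, small_spec())
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$variants, b$variants)
  expect_identical(a$deep$score$track, b$deep$score$track)
  expect_identical(a$deep$expression$matrix, b$deep$expression$matrix)
  c <- simulate_study(12, small_spec())
  expect_false(identical(a$genomes, c$genomes))
})

test_that("Markov calibration hits GC and obs/exp targets", {
  set.seed(911)
  for (tgt in list(c(0.41, 0.25), c(0.48, 0.34), c(0.50, 1.00))) {
    s <- c(x = generate_sequence(3e5, tgt[1], tgt[2]))
    expect_equal(gc_content(s), tgt[1], tolerance = 0.01)
    expect_equal(cpg_obs_exp(s), tgt[2], tolerance = 0.05)
  }
  expect_error(generate_sequence(100, 1.2, 0.3), "gc")
})

test_that("soft-masking changes only case", {
  set.seed(912)
  masked <- generate_sequence(50000, 0.45, 0.3, softmask_frac = 0.1)
  set.seed(912)
  plain <- generate_sequence(50000, 0.45, 0.3)
  expect_false(identical(masked, plain))
  expect_identical(toupper(masked), plain)
  frac <- mean(strsplit(masked, "")[[1]] %in% c("a", "c", "g", "t"))
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.15)
})

test_that("generate_chain_pair emits consistent assemblies and chains", {
  set.seed(913)
  g <- c(c1 = random_seq(12000, c("A", "C", "G", "T")),
         c2 = random_seq(9000, c("A", "C", "G", "T")))
  del <- intervals("c1", 4001, 5000)
  cp <- generate_chain_pair(g, deletions = del, shuffle = TRUE)
  # each truth row's A substring equals its B substring
  for (i in seq_len(nrow(cp$truth))) {
    tr <- cp$truth[i, ]
    expect_identical(substr(g[[tr$chrom]], tr$a_start, tr$a_end),
                     substr(cp$genome_b[[tr$b_chrom]], tr$b_start, tr$b_end))
  }
  # deleted bases are absent from B
  expect_equal(sum(nchar(cp$genome_b)), sum(nchar(g)) - 1000)
  # chains are internally consistent when re-read from disk
  p <- tempfile(fileext = ".chain")
  on.exit(unlink(p))
  write_chain(cp$chains_ab, p)
  expect_equal(length(read_chain(p)), length(cp$chains_ab))
})

test_that("plant_features places non-overlapping intervals per chromosome", {
  set.seed(914)
  feats <- plant_features(c(c1 = 1e5, c2 = 1e5))
  all_gr <- intervals(do.call(rbind, lapply(feats, gr_to_df)))
  expect_equal(covered_bases(all_gr), sum(width(all_gr)))  # no overlap
  expect_equal(length(feats$promoter), 16L)   # 8 per chromosome
  expect_true(all(width(feats$promoter) == 500))
  expect_true(all(width(feats$enhancer) == 600))
})

test_that("score-track generator recovers planted class means", {
  set.seed(915)
  feats <- plant_features(c(c1 = 2e5))
  means <- c(promoter = 0.2, promoter_flanking = -0.0064,
             enhancer = -0.026, background = 0.05)
  sc <- generate_score_track(feats, means, noise_sd = 0.2)
  fc <- feature_class_summary(sc$track, feats)
  for (i in seq_len(nrow(fc))) {
    cl <- fc$class[i]
    n <- sum(width(feats[[cl]]))
    expect_lt(abs(fc$mean_score[i] - means[[cl]]), 5 * 0.2 / sqrt(n))
  }
})

test_that("written study files parse back to the in-memory objects", {
  dir <- tempfile("study")
  on.exit(unlink(dir, recursive = TRUE))
  st <- simulate_study(13, small_spec(), dir = dir)
  sp1 <- names(st$genomes)[1]
  g <- read_fasta(file.path(dir, paste0(sp1, ".fa")))
  expect_identical(g, st$genomes[[sp1]])
  vcf <- read_vcf_snps(file.path(dir, paste0(sp1, ".vcf")))
  expect_equal(vcf$pos, st$variants[[sp1]]$pos)
  expect_equal(vcf$ref, st$variants[[sp1]]$ref)
  tr <- read_score_track(file.path(dir, "conservation.bedGraph"))
  expect_equal(sum(width(tr)), sum(width(st$deep$score$track)))
  m <- read_gct(file.path(dir, "expression.gct"))
  expect_equal(m, st$deep$expression$matrix, tolerance = 1e-12)
  blocks <- read_maf(file.path(dir, "alignment.maf"))
  expect_equal(length(blocks), length(st$deep$alignment$blocks))
  chains <- read_chain(file.path(dir, "a_to_b.chain"))
  expect_equal(length(chains), length(st$deep$chains$chains_ab))
  truth <- read.delim(file.path(dir, paste0(sp1, ".vcf.truth.tsv")))
  expect_equal(truth$pos, st$variants[[sp1]]$pos)
})

test_that("default_study_spec encodes the study conditions", {
  sp <- default_study_spec()
  expect_equal(length(unique(sp$species)), 12L)
  expect_equal(sum(sp$is_target), 12L)
  expect_equal(unique(sp$gc[sp$is_target]), 0.48)
  expect_equal(unique(sp$gc[!sp$is_target]), 0.41)
  expect_equal(unique(sp$obs_exp[sp$is_target]), 0.34)
  expect_equal(unique(sp$snp_per_kbp[sp$is_target]), 5)
  expect_equal(unique(sp$snp_per_kbp[!sp$is_target]), 3)
  expect_equal(attr(sp, "min_len"), 5e5)
  expect_equal(attr(sp, "max_len"), 1e6)
})
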