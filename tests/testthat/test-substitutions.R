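block_ <- function(a_txt, b_txt, a_start = 0, chrom = "c1",
                   a_strand = "+", a_src_size = 1000) {
  ua <- nchar(gsub("-", "", a_txt)); ub <- nchar(gsub("-", "", b_txt))
  list(score = NA_real_,
       rows = data.frame(
         src = c(paste0("spA.", chrom), "spB.c9"),
         start = c(a_start, 0), size = c(ua, ub),
         strand = c(a_strand, "+"), src_size = c(a_src_size, 1000),
         text = c(a_txt, b_txt)))
}

test_that("substitution extraction matches a per-column oracle", {
  set.seed(701)
  for (rep in 1:25) {
    n <- sample(40:120, 1)
    a <- sample(c("A", "C", "G", "T", "-", "N"), n, replace = TRUE,
                prob = c(.2, .2, .2, .2, .15, .05))
    b <- a
    mut <- runif(n) < 0.3
    b[mut] <- sample(c("A", "C", "G", "T", "-"), sum(mut), replace = TRUE)
    a_txt <- paste(a, collapse = ""); b_txt <- paste(b, collapse = "")
    st <- sample(0:500, 1)
    subs <- extract_substitutions(list(block_(a_txt, b_txt, a_start = st)),
                                  "spA", "spB", cpg_rule = "reference")
    # oracle: walk columns
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T") & a != b
    pos <- st + cumsum(a != "-")
    expect_equal(subs$pos, pos[ok])
    expect_equal(subs$ref, a[ok])
    expect_equal(subs$alt, b[ok])
    # reference-rule CpG flags from the gap-stripped A sequence
    sa <- a[a != "-"]
    La <- length(sa)
    cpg_a <- (sa == "C" & c(sa[-1], "") == "G") |
      (sa == "G" & c("", sa[-La]) == "C")
    idx_a <- cumsum(a != "-")[ok]
    expect_equal(subs$in_cpg, unname(cpg_a[idx_a]))
  }
})

test_that("species order symmetry: counts and CpG flags are mirrored", {
  set.seed(702)
  a <- random_seq(300, c("A", "C", "G", "T"))
  g <- c(c1 = a)
  aln <- generate_alignment_partner(g, rate = 0.03, kappa = 5,
                                    species = c("spA", "spB"))
  ab <- extract_substitutions(aln$blocks, "spA", "spB")
  ba <- extract_substitutions(aln$blocks, "spB", "spA")
  expect_equal(nrow(ab), nrow(ba))
  expect_equal(sort(paste0(ab$ref, ab$alt)), sort(paste0(ba$alt, ba$ref)))
  expect_equal(sum(ab$in_cpg), sum(ba$in_cpg))
})

test_that("minus-strand blocks are reverse-complemented whole", {
  # forward alignment: A = TACGG at positions 11..15, B differs at the C
  fwd <- block_("TACGG", "TATGG", a_start = 10)
  want <- extract_substitutions(list(fwd), "spA", "spB")
  # the same alignment stored on the minus strand of A
  rev_a <- chartr("ACGT", "TGCA",
                  paste(rev(strsplit("TACGG", "")[[1]]), collapse = ""))
  rev_b <- chartr("ACGT", "TGCA",
                  paste(rev(strsplit("TATGG", "")[[1]]), collapse = ""))
  bl <- block_(rev_a, rev_b, a_start = 1000 - 15, a_strand = "-")
  got <- extract_substitutions(list(bl), "spA", "spB")
  expect_equal(got$pos, want$pos)
  expect_equal(got$ref, want$ref)
  expect_equal(got$alt, want$alt)
  expect_equal(got$in_cpg, want$in_cpg)
})

test_that("either-rule flags deamination events that reference misses", {
  # A: TATGA (CpG destroyed), B: TACGA (CpG intact at the substituted site)
  bl <- block_("TATGA", "TACGA")
  ref_rule <- extract_substitutions(list(bl), "spA", "spB",
                                    cpg_rule = "reference")
  either <- extract_substitutions(list(bl), "spA", "spB")
  expect_equal(nrow(either), 1L)
  expect_false(ref_rule$in_cpg)
  expect_true(either$in_cpg)
})

test_that("read_maf validates blocks and reports line numbers", {
  p <- tempfile(fileext = ".maf")
  on.exit(unlink(p))
  writeLines(c("a score=1", "s spA.c1 0 5 + 100 ACGTA",
               "s spB.c1 0 4 + 100 ACG-A", ""), p)
  bl <- read_maf(p)[[1]]
  expect_equal(bl$rows$size, c(5, 4))
  writeLines(c("a", "s spA.c1 0 5 + 100 ACGTA",
               "s spB.c1 0 4 + 100 ACGA", ""), p)
  expect_error(read_maf(p), "ragged")
  writeLines(c("a", "s spA.c1 0 4 + 100 ACGTA", ""), p)
  expect_error(read_maf(p), "size disagrees")
  writeLines("s spA.c1 0 5 + 100 ACGTA", p)
  expect_error(read_maf(p), "outside a block")
})

test_that("MAF write/read round-trip preserves blocks", {
  set.seed(703)
  g <- c(c1 = random_seq(3000, c("A", "C", "G", "T")))
  aln <- generate_alignment_partner(g, rate = 0.01, block_size = 700)
  p <- tempfile(fileext = ".maf")
  on.exit(unlink(p))
  write_maf(aln$blocks, p)
  back <- read_maf(p)
  expect_equal(length(back), length(aln$blocks))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$rows$text, aln$blocks[[i]]$rows$text)
    expect_equal(back[[i]]$rows$start, aln$blocks[[i]]$rows$start)
  }
})

test_that("planted substitutions round-trip and respond to kappa", {
  set.seed(704)
  g <- c(c1 = generate_sequence(60000, 0.45, 0.5))
  aln <- generate_alignment_partner(g, rate = 0.01, kappa = 8)
  subs <- extract_substitutions(aln$blocks, "spA", "spB",
                                cpg_rule = "reference")
  truth <- aln$truth
  expect_equal(subs$pos, truth$pos)
  expect_equal(subs$ref, truth$ref)
  expect_equal(subs$alt, truth$alt)
  expect_equal(subs$in_cpg, truth$in_cpg)
  # kappa = 1 removes the CpG excess
  set.seed(705)
  aln1 <- generate_alignment_partner(g, rate = 0.01, kappa = 1)
  p8 <- percent_in_cpg(subs)$overall
  p1 <- percent_in_cpg(extract_substitutions(aln1$blocks, "spA", "spB",
                                             cpg_rule = "reference"))$overall
  expect_gt(p8, p1 + 10)
})

test_that("percent_in_cpg restricts to regions and handles empty input", {
  subs <- data.frame(chrom = c("c1", "c1", "c2"), pos = c(5, 50, 5),
                     ref = "C", alt = "T", in_cpg = c(TRUE, FALSE, FALSE))
  r <- percent_in_cpg(subs, regions = intervals("c1", 1, 10))
  expect_equal(r$by_chrom$n, 1L)
  expect_equal(r$overall, 100)
  empty <- percent_in_cpg(subs[0, ])
  expect_true(is.na(empty$overall))
})
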