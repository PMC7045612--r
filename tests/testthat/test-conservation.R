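random_track <- function(sizes, n = 30) {
  gr <- random_intervals(sizes, n)
  gr <- GenomicRanges::reduce(sort(gr))   # disjoint, one value per base
  mcols(gr)$score <- round(rnorm(length(gr)), 3)
  score_track(gr)
}

test_that("mean_score matches the per-base oracle on random tracks", {
  set.seed(601)
  sizes <- c(c1 = 300L, c2 = 200L)
  for (rep in 1:30) {
    track <- random_track(sizes)
    regions <- random_intervals(sizes, sample.int(6, 1))
    got <- mean_score(track, regions)
    want <- oracle_mean_score(track, regions, sizes)
    if (is.na(want)) {
      expect_true(is.na(got$mean))
      expect_equal(got$covered, 0L)
    } else {
      expect_equal(got$mean, want)
      expect_equal(got$accelerated, want < 0)
    }
  }
})

test_that("uncovered bases are excluded, not zero-filled", {
  track <- score_track(GRanges("c", IRanges(1, 10), score = 2))
  r <- mean_score(track, intervals("c", 6, 20))
  expect_equal(r$mean, 2)        # 5 scored bases, 10 unscored excluded
  expect_equal(r$covered, 5L)
  expect_true(is.na(mean_score(track, intervals("c", 50, 60))$mean))
})

test_that("mean_score is invariant under region splitting", {
  set.seed(602)
  sizes <- c(c1 = 400L)
  track <- random_track(sizes, 40)
  whole <- intervals("c1", 11, 390)
  cuts <- sort(sample(12:389, 5))
  parts <- intervals("c1", c(11, cuts), c(cuts - 1, 390))
  expect_equal(mean_score(track, parts)$mean, mean_score(track, whole)$mean)
})

test_that("spearman_cor matches stats::cor and cor.test", {
  set.seed(603)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    x <- sample(1:10, n, replace = TRUE)   # ties likely
    y <- x + rnorm(n)
    r <- spearman_cor(x, y)
    expect_equal(r$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
  x <- c(2.3, 1.1, 5.4, 3.3, 8, 0.2, 7.7, 4.1, 6, 9.5)
  y <- c(1.2, 0.7, 4.0, 5.1, 6.6, 0.1, 8.2, 2.2, 7.9, 9.1)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  r <- spearman_cor(x, y)
  expect_equal(r$rho, unname(ct$estimate), tolerance = 1e-12)
  tstat <- r$rho * sqrt((r$n - 2) / (1 - r$rho^2))
  expect_equal(r$p_value, 2 * pt(-abs(tstat), r$n - 2))
})

test_that("exact permutation p-value matches cor.test for small n", {
  x <- c(3, 1, 4, 2, 5)
  y <- c(2, 1, 5, 3, 4)
  r <- spearman_cor(x, y, p_method = "exact")
  ct <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(r$rho, unname(ct$estimate))
  expect_equal(r$p_value, ct$p.value, tolerance = 1e-12)
  expect_error(spearman_cor(1:9, 9:1, p_method = "exact"), "n <= 8")
  expect_true(is.na(spearman_cor(c(1, 1, 1), c(1, 2, 3))$rho))
})

test_that("rank_chromosomes orders ascending with name tie-break", {
  df <- data.frame(chrom = c("b", "a", "c"), mean_score = c(0.5, -0.2, 0.5))
  out <- rank_chromosomes(df)
  expect_equal(out$chrom, c("a", "b", "c"))
  expect_error(rank_chromosomes(df[1, ]), "at least two")
})

test_that("feature_class_summary distinguishes base and feature weighting", {
  track <- score_track(GRanges("c", IRanges(c(1, 11), c(10, 12)),
                               score = c(1, 4)))
  cls <- list(f = intervals(c("c", "c"), c(1, 11), c(10, 12)))
  by_base <- feature_class_summary(track, cls)
  expect_equal(by_base$mean_score, (10 * 1 + 2 * 4) / 12)
  by_feat <- feature_class_summary(track, cls, weight = "feature")
  expect_equal(by_feat$mean_score, (1 + 4) / 2)
})

test_that("score_track validates overlap and finiteness", {
  expect_error(score_track(GRanges("c", IRanges(1, 5))), "score")
  expect_error(score_track(GRanges("c", IRanges(1, 5), score = NaN)),
               "finite")
  expect_error(score_track(GRanges("c", IRanges(c(1, 3), c(5, 8)),
                                   score = c(1, 2))), "overlap")
})
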