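# A hand-built chain: target c1[100,400) aligns to query q1 with one
# 100-base block, a 50-base target-only gap (dt), a 100-base block, a
# 30-base query-only gap (dq), then a 50-base block.
hand_chain <- function() {
  list(score = 1000, t_name = "c1", t_size = 1000,
       t_start = 100, t_end = 400,
       q_name = "q1", q_size = 800, q_strand = "+",
       q_start = 200, q_end = 480, id = "1",
       blocks = data.frame(size = c(100, 100, 50),
                           dt = c(50, 0, 0), dq = c(0, 30, 0)))
}

test_that("lift through a hand-built chain matches hand-computed targets", {
  ch <- hand_chain()
  res <- lift_intervals(intervals("c1", 101, 150), list(ch))
  expect_equal(res$summary$status, "lifted")
  expect_equal(start(res$targets[[1]]), 201)
  expect_equal(end(res$targets[[1]]), 250)
  # interval spanning the dt gap: bases 151..250 -> 50 mapped in block 1,
  # bases 201..250 land in block 2 at q 300+.. (after dq-free first block)
  res2 <- lift_intervals(intervals("c1", 151, 280), list(ch))
  expect_equal(res2$summary$status, "partially_deleted")
  expect_equal(res2$summary$fraction, 1 - 50 / 130)
  expect_equal(start(res2$targets[[1]]), 251)
  expect_equal(end(res2$targets[[1]]), 330)
})

test_that("per-base lifts match the naive chain-walk oracle", {
  set.seed(401)
  ch <- hand_chain()
  for (p in sort(sample(100:399, 60))) {
    res <- lift_intervals(intervals("c1", p + 1, p + 1), list(ch),
                          min_match = 1)
    want <- oracle_map_base(ch, p)
    if (is.na(want)) {
      expect_equal(res$summary$status, "unmapped")
    } else {
      expect_equal(start(res$targets[[1]]), want + 1)
      expect_equal(width(res$targets[[1]]), 1)
    }
  }
})

test_that("minus-strand query coordinates are reported forward", {
  ch <- hand_chain()
  ch$q_strand <- "-"
  res <- lift_intervals(intervals("c1", 101, 150), list(ch))
  # reversed-strand q positions 201..250 map to forward 800-250+1..800-201+1
  expect_equal(start(res$targets[[1]]), 800 - 250 + 1)
  expect_equal(end(res$targets[[1]]), 800 - 201 + 1)
  for (p in c(100, 123, 250, 399)) {
    want <- oracle_map_base(ch, p)
    if (is.na(want)) next
    res1 <- lift_intervals(intervals("c1", p + 1, p + 1), list(ch),
                           min_match = 1)
    expect_equal(start(res1$targets[[1]]), want + 1)
  }
})

test_that("our lift agrees with rtracklayer::liftOver on a written chain", {
  ch <- hand_chain()
  path <- tempfile(fileext = ".chain")
  on.exit(unlink(path))
  write_chain(list(ch), path)
  rt <- rtracklayer::import.chain(path)
  src <- intervals(rep("c1", 3), c(101, 151, 351), c(150, 300, 390))
  rt_res <- rtracklayer::liftOver(src, rt)
  our <- lift_intervals(src, list(ch), min_match = 1e-9,
                        allow_multiple = TRUE)
  for (i in seq_along(src)) {
    a <- sort(GenomicRanges::reduce(rt_res[[i]]))
    b <- our$targets[[i]]
    expect_equal(gr_to_df(b), gr_to_df(a), info = paste("interval", i))
  }
})

test_that("chain parse errors carry line numbers and spans are verified", {
  p <- tempfile()
  on.exit(unlink(p))
  writeLines(c("chain 100 c1 1000 + 0 100 q1 1000 + 0 90", "100", ""), p)
  expect_error(read_chain(p), "inconsistent chain spans")
  writeLines(c("notachain 1 2 3"), p)
  expect_error(read_chain(p), "line 1")
  writeLines(c("chain 100 c1 1000 - 0 100 q1 1000 + 0 100", "100", ""), p)
  expect_error(read_chain(p), "target strand")
})

test_that("chain write/read round-trip is lossless", {
  ch <- hand_chain()
  p <- tempfile(fileext = ".chain")
  on.exit(unlink(p))
  write_chain(list(ch), p)
  back <- read_chain(p)
  expect_equal(length(back), 1L)
  expect_equal(back[[1]][names(ch)], ch)
})

test_that("min_match separates lifted, partially_deleted, split, unmapped", {
  ch <- hand_chain()
  # 151..260: 50/110 bases in the dt gap -> partial
  r <- lift_intervals(intervals("c1", 151, 260), list(ch), min_match = 0.5)
  expect_equal(r$summary$status, "partially_deleted")
  r2 <- lift_intervals(intervals("c1", 151, 260), list(ch), min_match = 0.9)
  expect_equal(r2$summary$status, "unmapped")
  r3 <- lift_intervals(intervals("c1", 501, 600), list(ch))
  expect_equal(r3$summary$status, "unmapped")
  # an interval crossing the dq gap maps to two non-adjacent q pieces
  r4 <- lift_intervals(intervals("c1", 341, 360), list(ch), min_match = 1)
  expect_equal(r4$summary$status, "split")
  expect_equal(r4$summary$n_targets, 0L)
  r5 <- lift_intervals(intervals("c1", 341, 360), list(ch), min_match = 1,
                       allow_multiple = TRUE)
  expect_equal(r5$summary$status, "lifted")
  expect_equal(r5$summary$n_targets, 2L)
})

test_that("reciprocal_filter keeps exact round-trips and drops deletions", {
  set.seed(402)
  g <- c(c1 = random_seq(20000, c("A", "C", "G", "T")),
         c2 = random_seq(15000, c("A", "C", "G", "T")))
  del <- intervals("c1", 8001, 9000)
  cp <- generate_chain_pair(g, deletions = del, shuffle = TRUE)
  probes <- intervals(c("c1", "c1", "c2"),
                      c(1001, 8101, 2001), c(1500, 8600, 2500))
  kept <- reciprocal_filter(probes, cp$chains_ab, cp$chains_ba)
  expect_equal(gr_to_df(kept), gr_to_df(probes[c(1, 3)]))
  # overlap mode also keeps the surviving probes
  kept2 <- reciprocal_filter(probes, cp$chains_ab, cp$chains_ba,
                             mode = "overlap", min_overlap = 0.95)
  expect_equal(gr_to_df(kept2), gr_to_df(probes[c(1, 3)]))
})
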