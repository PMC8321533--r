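flag_windows <- function(win, idx) {
  f <- rep(FALSE, nrow(win)); f[idx] <- TRUE; f
}

grid20 <- function(n, chrom = "c1") {
  window_fixture(rep(0, n), chrom = chrom)
}

test_that("flagging threshold is inclusive and NA-safe", {
  z <- c(2.0, 1.99, NA, 3.5, -2.5)
  expect_equal(call_divergent_windows(z, 2), c(TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("hand-traced merge fixtures reproduce exactly", {
  # six consecutive flagged 20-kb windows -> one 120-kb island
  win <- grid20(20)
  io <- merge_and_filter(win, flag_windows(win, 3:8), island_params())
  expect_equal(nrow(io), 1L)
  expect_equal(io$end - io$start, 120000)
  expect_equal(io$start, (3 - 1) * 20000)

  # 80-kb and 100-kb blocks, 200-kb apart: neither is > 100 kb (strict)
  win <- grid20(40)
  flags <- flag_windows(win, c(1:4, 15:19))
  io <- merge_and_filter(win, flags, island_params())
  expect_equal(nrow(io), 0L)

  # two 120-kb islands 900 kb apart; second merge at 1 Mb bridges them
  win <- grid20(120)
  flags <- flag_windows(win, c(1:6, 52:57))  # gap = 45 windows = 900 kb
  io1 <- merge_and_filter(win, flags, island_params())
  expect_equal(nrow(io1), 2L)
  io2 <- merge_and_filter(win, flags,
                          island_params(second_merge_gap = 1e6))
  expect_equal(nrow(io2), 1L)
  expect_equal(io2$end - io2$start, 120000 + 900000 + 120000)

  # empty flag set
  expect_equal(nrow(merge_and_filter(win, flag_windows(win, integer(0)),
                                     island_params())), 0L)
})

test_that("merging never crosses chromosomes", {
  cl <- c(c1 = 2e5, c2 = 2e5)
  win <- make_windows(cl, 20000)
  win <- tibble::as_tibble(win[, c("chrom", "start", "end")])
  attr(win, "chrom_lengths") <- cl
  flags <- rep(TRUE, nrow(win))
  io <- merge_and_filter(win, flags, island_params())
  expect_equal(nrow(io), 2L)
  expect_equal(sort(io$chrom), c("c1", "c2"))
})

test_that("caller equals interval-union oracle on random flag patterns", {
  set.seed(61)
  for (rep in 1:200) {
    n <- sample(10:100, 1)
    win <- grid20(n)
    flags <- runif(n) < 0.3
    gap <- sample(c(0, 20000, 60000, 100000), 1)
    minlen <- sample(c(0, 50000, 100000), 1)
    io <- merge_and_filter(win, flags,
                           island_params(merge_gap = gap,
                                         min_length = minlen))
    fw <- win[flags, ]
    om <- oracle_merge(fw$start, fw$end, gap)
    om <- om[om$end - om$start > minlen, , drop = FALSE]
    expect_equal(nrow(io), nrow(om))
    expect_equal(io$start, om$start)
    expect_equal(io$end, om$end)
  }
})

test_that("island calling is idempotent and monotone", {
  set.seed(62)
  n <- 200
  win <- window_fixture(c(runif(n, 0, 0.2)))
  win$fst_p1_p2[30:44] <- runif(15, 0.7, 0.9)
  win$fst_p1_p2[100:110] <- runif(11, 0.5, 0.9)
  win <- add_zfst(win)
  par <- island_params(second_merge_gap = 1e6)
  io <- call_islands(win, "zfst_p1_p2", par)
  # idempotence: merging the merged set changes nothing
  re <- merge_regions(io, gap = par$merge_gap)
  expect_equal(re$start, io$start)
  expect_equal(re$end, io$end)
  # monotonicity in threshold and merge gap
  bp <- function(params) {
    sum({x <- call_islands(win, "zfst_p1_p2", params); x$end - x$start})
  }
  expect_true(bp(island_params(z_threshold = 1)) >=
                bp(island_params(z_threshold = 2)))
  expect_true(bp(island_params(z_threshold = 3)) <=
                bp(island_params(z_threshold = 2)))
  expect_true(bp(island_params(merge_gap = 200000)) >=
                bp(island_params(merge_gap = 60000)))
  # every flagged window inside an island meets the threshold
  cls <- classify_windows(win, io)
  flagged <- call_divergent_windows(win$zfst_p1_p2, 2)
  expect_true(all(win$zfst_p1_p2[flagged & cls == "IoD"] >= 2))
})

test_that("inside/outside contrast reports medians, percent change and p", {
  set.seed(63)
  win <- grid20(100)
  win$stat <- rnorm(100, 10, 0.1)
  io <- region_set("c1", 0, 20 * 20000)
  ctr <- compare_inside_outside(win, io, "stat")
  expect_equal(ctr$n_in, 20L); expect_equal(ctr$n_out, 80L)
  expect_equal(ctr$pct_change,
               100 * (ctr$mean_in - ctr$mean_out) / ctr$mean_out)
  expect_gt(ctr$p_value, 0.001)  # identical distributions
  # shifted statistic is detected
  win$stat[1:20] <- win$stat[1:20] + 5
  ctr2 <- compare_inside_outside(win, io, "stat")
  expect_lt(ctr2$p_value, 1e-10)
  expect_gt(ctr2$pct_change, 0)
  # degenerate: everything inside
  io_all <- region_set("c1", 0, 100 * 20000)
  ctr3 <- compare_inside_outside(win, io_all, "stat")
  expect_true(is.na(ctr3$p_value))
})
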