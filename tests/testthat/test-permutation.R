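test_that("randomization preserves sizes and chromosomes, seeded runs repeat", {
  cl <- c(c1 = 1e5, c2 = 5e4)
  r <- region_set(c("c1", "c1", "c2"), c(0, 40000, 0),
                  c(10000, 60000, 25000), chrom_lengths = cl)
  set.seed(42); a <- randomize_regions(r)
  set.seed(42); b <- randomize_regions(r)
  expect_equal(a$start, b$start)
  expect_equal(sort(a$end - a$start), sort(r$end - r$start))
  expect_equal(table(a$chrom), table(r$chrom))
  expect_true(all(a$end <= cl[a$chrom]))
  # a region as long as its chromosome has a single legal placement
  full <- region_set("c1", 0, 1e5, chrom_lengths = cl)
  set.seed(9)
  expect_equal(randomize_regions(full)$start, 0)
  expect_error(randomize_regions(region_set("c1", 0, 10)), "lengths")
})

test_that("placements are uniform over the legal positions", {
  # 1-unit region on a 10-unit chromosome: 10 legal starts
  r <- region_set("c1", 0, 1, chrom_lengths = c(c1 = 10))
  set.seed(77)
  starts <- replicate(10000, randomize_regions(r)$start)
  tab <- table(factor(starts, levels = 0:9))
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("overlap statistic equals the exhaustive pairwise oracle", {
  set.seed(81)
  cl <- c(c1 = 1e5, c2 = 1e5, c3 = 5e4)
  for (rep in 1:50) {
    q <- random_regions(5, cl); r <- random_regions(3, cl)
    expect_equal(overlap_stat(q, r), oracle_overlap_count(q, r))
    # invariant to the order of intervals
    perm <- sample(nrow(q))
    expect_equal(overlap_stat(q[perm, ], r), overlap_stat(q, r))
  }
  # disjoint chromosomes and containment
  q <- region_set("c1", 10, 20); r <- region_set("c2", 10, 20)
  expect_equal(overlap_stat(q, r), 0)
  q2 <- region_set(c("c1", "c1"), c(5, 30), c(10, 40))
  expect_equal(overlap_stat(q2, region_set("c1", 0, 100)), 2)
})

test_that("overlap statistic agrees with IRanges on random fixtures", {
  skip_if_not_installed("IRanges")
  set.seed(82)
  cl <- c(c1 = 1e5, c2 = 8e4)
  for (rep in 1:20) {
    q <- random_regions(8, cl); r <- random_regions(6, cl)
    n_ir <- 0; bp_ir <- 0
    for (ch in names(cl)) {
      qi <- IRanges::IRanges(q$start[q$chrom == ch] + 1,
                             q$end[q$chrom == ch])
      ri <- IRanges::IRanges(r$start[r$chrom == ch] + 1,
                             r$end[r$chrom == ch])
      n_ir <- n_ir + sum(IRanges::countOverlaps(qi, ri) > 0)
      bp_ir <- bp_ir + sum(IRanges::width(
        IRanges::intersect(IRanges::reduce(qi), IRanges::reduce(ri))))
    }
    expect_equal(overlap_stat(q, r), n_ir)
    expect_equal(overlap_stat(q, r, "bp_overlap"), bp_ir)
  }
})

test_that("merge_regions agrees with IRanges::reduce under gap bridging", {
  skip_if_not_installed("IRanges")
  set.seed(83)
  cl <- c(c1 = 2e5)
  for (gap in c(0, 500, 5000)) {
    x <- random_regions(12, cl)
    m <- merge_regions(x, gap = gap)
    ir <- IRanges::reduce(IRanges::IRanges(x$start + 1, x$end),
                          min.gapwidth = gap + 1)
    expect_equal(m$start, IRanges::start(ir) - 1)
    expect_equal(m$end, IRanges::end(ir))
  }
})

test_that("permutation p-values match exact enumeration on a tiny chromosome", {
  # query of length 2 on a chromosome of length 6: 5 legal starts,
  # reference fixed at [2, 4): overlap for starts 1, 2, 3 -> P = 3/5
  cl <- c(c1 = 6)
  q <- region_set("c1", 0, 2, chrom_lengths = cl)
  r <- region_set("c1", 2, 4, chrom_lengths = cl)
  pt <- perm_test(q, r, cl, n_perm = 4000, randomize = "A", seed = 4)
  # observed overlap is 0 (start 0 does not reach position 2):
  expect_equal(pt$observed, 0)
  # null >= 0 always, so p = 1
  expect_equal(pt$p_empirical, 1)
  # for the "less" side: #(null <= 0) estimates P(no overlap) = 2/5
  pt_less <- perm_test(q, r, cl, n_perm = 4000, randomize = "A",
                       alternative = "less", seed = 4)
  expect_equal(pt_less$p_empirical, 2 / 5, tolerance = 0.05)
  expect_equal(pt$null_mean, 3 / 5, tolerance = 0.05)
})

test_that("p-values are valid and z is NA for constant nulls", {
  cl <- c(c1 = 100)
  a <- region_set("c1", 0, 100, chrom_lengths = cl)  # covers everything
  b <- region_set("c1", 10, 20, chrom_lengths = cl)
  pt <- perm_test(a, b, cl, n_perm = 50, seed = 1)
  expect_true(is.na(pt$z_score))
  expect_equal(pt$p_empirical, 1 / 51 * sum(rep(1, 51)))  # all ties -> 1
  expect_gte(pt$p_empirical, 1 / 51)
})

test_that("randomize both vs A give compatible fold estimates", {
  set.seed(85)
  cl <- c(c1 = 2e5, c2 = 2e5)
  a <- random_regions(6, cl, min_len = 5000, max_len = 20000)
  b <- random_regions(6, cl, min_len = 5000, max_len = 20000)
  pa <- perm_test(a, b, cl, n_perm = 400, randomize = "A", seed = 10)
  pb <- perm_test(a, b, cl, n_perm = 400, randomize = "both", seed = 11)
  expect_equal(pa$null_mean, pb$null_mean, tolerance = 0.35)
})

test_that("non-overlapping randomization mode yields disjoint placements", {
  cl <- c(c1 = 1e4)
  r <- region_set(c("c1", "c1", "c1"), c(0, 0, 0),
                  c(2000, 2000, 2000), chrom_lengths = cl)
  set.seed(3)
  for (i in 1:20) {
    x <- randomize_regions(r, allow_overlap = FALSE)
    o <- order(x$start)
    expect_true(all(x$start[o][-1] >= x$end[o][-3]))
  }
})
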