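test_that("simulation parameters encode the window regimes", {
  p <- sim_params("sympatric")
  tr <- p$truth
  expect_setequal(unique(tr$class), c("background", "barrier"))
  # barrier: no homogenization; background: effective time reduced
  expect_true(all(tr$t_eff[tr$class == "barrier"] == p$t))
  expect_true(all(tr$t_eff[tr$class == "background"] ==
                    p$t * (1 - p$g)))
  expect_equal(tr$F_exp,
               1 - exp(-tr$t_eff / (3 * p$Ne * tr$lambda)))
  expect_true(all(tr$F_exp >= 0 & tr$F_exp < 1))
  # the drift-only targets: background ~0.21, barrier ~0.93
  expect_equal(unique(tr$F_exp[tr$class == "background"]), 0.21,
               tolerance = 0.01)
  expect_equal(unique(tr$F_exp[tr$class == "barrier"]), 0.93,
               tolerance = 0.01)
  expect_error(sim_params("sympatric", g = 1.2), "g <")

  pa <- sim_params("allopatric")
  expect_setequal(unique(pa$truth$class),
                  c("background", "lowrec_background"))
  expect_equal(pa$g, 0)
})

test_that("fixed seeds reproduce byte-identical simulations", {
  p <- sim_params("sympatric", chrom_lengths = c(chr1 = 5e5))
  d1 <- simulate_dataset(p, dir = NULL, seed = 5)
  d2 <- simulate_dataset(p, dir = NULL, seed = 5)
  expect_identical(d1$freq, d2$freq)
  expect_identical(d1$gt, d2$gt)
  d3 <- simulate_dataset(p, dir = NULL, seed = 6)
  expect_false(identical(d1$freq, d3$freq))
})

test_that("haploids are never heterozygous; diploids follow HW at p = 0.5", {
  set.seed(21)
  freq <- matrix(0.5, 5000, 2, dimnames = list(NULL, c("pop1", "pop2")))
  st <- sample_table(c("h1", "d1"), c("pop1", "pop2"), c(1L, 2L))
  gt <- sample_genotypes(freq, st)
  expect_true(all(gt[, "h1"] %in% c("0", "1")))
  expect_equal(mean(gt[, "d1"] == "0/1"), 0.5, tolerance = 0.03)
  # p = 1: all alt
  gt1 <- sample_genotypes(matrix(1, 10, 2,
                                 dimnames = list(NULL, c("pop1", "pop2"))),
                          st)
  expect_true(all(gt1[, "h1"] == "1") && all(gt1[, "d1"] == "1/1"))
})

test_that("no divergence means no structure: F ~ 0", {
  set.seed(22)
  p <- sim_params("neutral", t = 0, chrom_lengths = c(chr1 = 2e6))
  expect_true(all(p$truth$F_exp == 0))
  sim <- simulate_frequencies(p)
  sc <- sample_site_counts(sim$freq, n_chromosomes(p$samples),
                           sim$sites, p$chrom_lengths)
  cmp <- site_fst_components(sc$alt_count[, 1], sc$called_count[, 1],
                             sc$alt_count[, 2], sc$called_count[, 2])
  ok <- !is.na(cmp$den) & cmp$den > 0
  expect_equal(sum(cmp$num[ok]) / sum(cmp$den[ok]), 0, tolerance = 0.02)
})

test_that("moment recovery: class-level Hudson FST matches F_exp, pi scales with lambda", {
  set.seed(23)
  # mu = 0 isolates the drift component that F_exp describes; enough
  # windows for >= 5e4 sites per class
  p <- sim_params("sympatric", chrom_lengths = c(chr1 = 1.2e8), mu = 0,
                  block_windows = 3000, theta_anc = 0.006)
  sim <- simulate_frequencies(p)
  sc <- sample_site_counts(sim$freq, n_chromosomes(p$samples),
                           sim$sites, p$chrom_lengths)
  wmap <- match(paste0(sim$sites$chrom, ":",
                       (sim$sites$pos - 1) %/% 2e4 * 2e4),
                paste0(p$truth$chrom, ":", p$truth$start))
  cls <- p$truth$class[wmap]
  cmp <- site_fst_components(sc$alt_count[, 1], sc$called_count[, 1],
                             sc$alt_count[, 2], sc$called_count[, 2])
  for (cl in c("background", "barrier")) {
    expect_gt(sum(cls == cl), 5e4)  # placed sites per class
    i <- cls == cl & !is.na(cmp$den) & cmp$den > 0
    fhat <- sum(cmp$num[i]) / sum(cmp$den[i])
    expect_equal(fhat, unique(p$truth$F_exp[p$truth$class == cl]),
                 tolerance = 0.02)
  }
  # lambda scales ancestral diversity: site density ratio ~ lambda
  dens <- table(cls) / table(p$truth$class)[names(table(cls))]
  expect_equal(unname(dens["barrier"] / dens["background"]), p$lambda,
               tolerance = 0.05)
})

test_that("written artifacts are consistent and round-trip", {
  p <- sim_params("sympatric", chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                  block_windows = 10)
  dir <- file.path(tempdir(), "simout")
  d <- simulate_dataset(p, dir = dir, seed = 8)
  expect_true(all(file.exists(unlist(d$paths))))
  # truth BED covers exactly the barrier windows
  bed <- read_bed(d$paths$truth_bed)
  tr <- d$truth[d$truth$class == "barrier", ]
  expect_equal(region_bp(bed), sum(tr$end - tr$start))
  # VCF round trip preserves counts
  st <- load_sample_table(d$paths$samples)
  sc <- read_sites(d$paths$vcf, st)
  sc0 <- sim_site_counts(d)
  expect_equal(sc$alt_count, sc0$alt_count)
  expect_equal(sc$called_count, sc0$called_count)
  cl <- read_chrom_lengths(d$paths$chrom_lengths)
  expect_equal(cl, c(chr1 = 1e6, chr2 = 1e6))
  # empty simulation still writes a parseable header-only VCF
  p0 <- sim_params("neutral", t = 0, theta_anc = 0,
                   chrom_lengths = c(chr1 = 1e5))
  d0 <- simulate_dataset(p0, dir = file.path(tempdir(), "simempty"),
                         seed = 1)
  sc_empty <- read_sites(d0$paths$vcf, st)
  expect_equal(n_sites(sc_empty), 0L)
})
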