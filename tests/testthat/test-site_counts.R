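samples3 <- function() {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tpopulation\tploidy",
               "a1\tA\t2", "a2\tA\t2", "b1\tB\t1"), path)
  load_sample_table(path)
}

test_that("genotypes are counted per population with mixed ploidy", {
  st <- samples3()
  vcf <- write_fixture_vcf(
    c(vcf_record("chr1", 100, "A", "G", c("0/1", "1/1", "0")),
      vcf_record("chr1", 200, "C", "T", c("0/0", "./.", "1")),
      vcf_record("chr1", 300, "G", "A", c("0|1", "0/0", "1/1"))),
    c("a1", "a2", "b1"), contigs = c(chr1 = 1000))
  sc <- read_sites(vcf, st)
  expect_equal(n_sites(sc), 3L)
  # site 1: A has 0/1 + 1/1 = 3 alt of 4; B haploid "0" = 0 of 1
  expect_equal(sc$alt_count[1, ], c(A = 3, B = 0))
  expect_equal(sc$called_count[1, ], c(A = 4, B = 1))
  # site 2: missing diploid removes two alleles from A
  expect_equal(sc$called_count[2, ], c(A = 2, B = 1))
  expect_equal(sc$alt_count[2, ], c(A = 0, B = 1))
  # site 3: haploid homozygous-style 1/1 counts a single chromosome
  expect_equal(sc$alt_count[3, ], c(A = 1, B = 1))
  expect_equal(sc$called_count[3, ], c(A = 4, B = 1))
  expect_equal(attr(sc, "chrom_lengths"), c(chr1 = 1000))
})

test_that("multiallelic, non-SNP and filter-failed records are dropped and counted", {
  st <- samples3()
  vcf <- write_fixture_vcf(
    c(vcf_record("chr1", 100, "A", "G,T", c("0/1", "1/2", "0")),
      vcf_record("chr1", 200, "AT", "A", c("0/1", "0/0", "0")),
      vcf_record("chr1", 300, "A", "G", c("0/1", "0/0", "0"),
                 filter = "LowQual"),
      vcf_record("chr1", 400, "A", "G", c("0/1", "0/0", "0"))),
    c("a1", "a2", "b1"))
  sc <- read_sites(vcf, st)
  expect_equal(n_sites(sc), 1L)
  rep_ <- attr(sc, "filter_report")
  counts <- setNames(rep_$n, rep_$filter)
  expect_equal(counts[["multiallelic"]], 1L)
  expect_equal(counts[["non_snp"]], 1L)
  expect_equal(counts[["filter_failed"]], 1L)
  expect_equal(counts[["retained"]], 1L)
  # dropped records = sum of per-filter counters
  expect_equal(4L - counts[["retained"]],
               counts[["multiallelic"]] + counts[["non_snp"]] +
                 counts[["filter_failed"]] + counts[["haploid_het"]])
})

test_that("sites with heterozygous haploid calls are dropped entirely", {
  st <- samples3()
  vcf <- write_fixture_vcf(
    c(vcf_record("chr1", 100, "A", "G", c("0/1", "1/1", "0/1")),
      vcf_record("chr1", 200, "A", "G", c("0/1", "1/1", "1/1"))),
    c("a1", "a2", "b1"))
  sc <- read_sites(vcf, st)
  expect_equal(n_sites(sc), 1L)
  expect_equal(sc$pos, 200L)
  expect_equal(attr(sc, "filter_report")$n[
    attr(sc, "filter_report")$filter == "haploid_het"], 1L)
  # with the filter off, the het haploid call is treated as missing
  sc2 <- read_sites(vcf, st, drop_haploid_hets = FALSE)
  expect_equal(n_sites(sc2), 2L)
  expect_equal(sc2$called_count[1, "B"], c(B = 0))
})

test_that("haploid-het filtering is the identity without haploid samples", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tpopulation\tploidy", "a1\tA\t2", "b1\tB\t2"), path)
  st <- load_sample_table(path)
  vcf <- write_fixture_vcf(
    c(vcf_record("chr1", 100, "A", "G", c("0/1", "0/1"))),
    c("a1", "b1"))
  expect_equal(n_sites(read_sites(vcf, st)), 1L)
})

test_that("missing table samples in the VCF header raise an error", {
  st <- samples3()
  vcf <- write_fixture_vcf(
    c(vcf_record("chr1", 100, "A", "G", c("0/1", "1/1"))),
    c("a1", "a2"))
  expect_error(read_sites(vcf, st), "absent from VCF")
})

test_that("round trip: write retained genotypes, re-read, identical counts", {
  set.seed(11)
  p <- sim_params("neutral", chrom_lengths = c(chr1 = 4e5))
  d <- simulate_dataset(p, dir = tempdir(), seed = 3)
  sc_direct <- sim_site_counts(d)
  st <- load_sample_table(d$paths$samples)
  sc_vcf <- read_sites(d$paths$vcf, st)
  expect_equal(sc_vcf$pos, sc_direct$pos)
  expect_equal(sc_vcf$alt_count, sc_direct$alt_count)
  expect_equal(sc_vcf$called_count, sc_direct$called_count)
  # alt + ref = called at every site and population
  ref_count <- sc_vcf$called_count - sc_vcf$alt_count
  expect_true(all(ref_count >= 0))
  expect_equal(sc_vcf$alt_count + ref_count, sc_vcf$called_count)
})

test_that("a header-only VCF yields an empty, valid site_counts", {
  st <- samples3()
  vcf <- write_fixture_vcf(character(0), c("a1", "a2", "b1"),
                           contigs = c(chr1 = 500))
  sc <- read_sites(vcf, st)
  expect_equal(n_sites(sc), 0L)
  expect_equal(colnames(sc$alt_count), c("A", "B"))
})
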