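#' Per-site per-population allele counts
#'
#' `site_counts` is the atomic container all estimators consume: for each
#' retained biallelic SNP it stores, per population, the number of
#' successfully genotyped alleles (`called_count`) and how many of those
#' are the alternate allele (`alt_count`).  Missing genotypes reduce
#' `called_count`; a missing diploid genotype removes two alleles.
#'
#' @param chrom,pos site coordinates (`pos` 1-based, as in VCF).
#' @param ref,alt single-nucleotide alleles.
#' @param alt_count,called_count integer matrices (sites x populations)
#'   with population names as columns.
#' @param chrom_lengths optional named chromosome lengths.
#' @param filter_report optional tibble of per-filter drop counters.
#' @return A list of class `site_counts` with elements `chrom`, `pos`,
#'   `ref`, `alt`, `alt_count`, `called_count`, `populations`.
#' @export
site_counts <- function(chrom, pos, ref, alt, alt_count, called_count,
                        chrom_lengths = NULL, filter_report = NULL) {
  alt_count <- as.matrix(alt_count)
  called_count <- as.matrix(called_count)
  stopifnot(identical(dim(alt_count), dim(called_count)),
            length(chrom) == nrow(alt_count),
            length(pos) == nrow(alt_count))
  if (any(alt_count > called_count) || any(alt_count < 0)) {
    stop("invalid counts: need 0 <= alt_count <= called_count")
  }
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt),
         alt_count = alt_count, called_count = called_count,
         populations = colnames(alt_count)),
    chrom_lengths = chrom_lengths,
    filter_report = filter_report,
    class = "site_counts"
  )
}

#' @export
print.site_counts <- function(x, ...) {
  cat("<site_counts> ", length(x$pos), " biallelic SNPs, ",
      length(x$populations), " populations (",
      paste(x$populations, collapse = ", "), ")\n", sep = "")
  fr <- attr(x, "filter_report")
  if (!is.null(fr)) {
    cat("filters:", paste(sprintf("%s=%d", fr$filter, fr$n), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' @export
n_sites <- function(x) UseMethod("n_sites")

#' @export
n_sites.site_counts <- function(x) length(x$pos)

#' Read biallelic SNPs from a VCF into per-population allele counts
#'
#' Applies the site filters of the study design: only biallelic
#' single-nucleotide records are kept, records failing their VCF FILTER
#' are skipped, and (when `drop_haploid_hets = TRUE`) any site where a
#' haploid sample carries a heterozygous diploid-style call is dropped
#' entirely -- such calls are genotyping artifacts, typically from
#' cross-mapping reads, and taint the whole site.
#'
#' Haploid genotypes may be encoded either as a single allele (`0`, `1`)
#' or as a homozygous diploid call (`0/0`, `1/1`); both contribute one
#' chromosome.  Phased separators (`|`) are accepted throughout.
#'
#' @param vcf_path path to a VCF (plain or gzipped).
#' @param samples a [sample_table()]; every sample must be present in the
#'   VCF header.
#' @param drop_haploid_hets drop sites with heterozygous haploid calls
#'   (default TRUE).
#' @param keep_filter FILTER values treated as pass (default `.` and
#'   `PASS`).
#' @return A [site_counts()] object.  The `filter_report` attribute
#'   tabulates dropped records per filter; the `chrom_lengths` attribute
#'   is populated from `##contig` header lines when present.
#' @export
read_sites <- function(vcf_path, samples, drop_haploid_hets = TRUE,
                       keep_filter = c(".", "PASS")) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_field <- vcf@gt
  if (nrow(fix) == 0 || is.null(gt_field) || ncol(gt_field) < 2) {
    # header-only VCF: empty but valid
    pops <- populations(samples)
    empty <- matrix(integer(), 0, length(pops), dimnames = list(NULL, pops))
    return(site_counts(character(), integer(), character(), character(),
                       empty, empty,
                       chrom_lengths = contig_lengths_from_meta(vcf@meta),
                       filter_report = empty_filter_report()))
  }
  vcf_samples <- colnames(gt_field)[-1]
  missing_samples <- setdiff(samples$sample, vcf_samples)
  if (length(missing_samples)) {
    stop("sample(s) in table absent from VCF header: ",
         paste(missing_samples, collapse = ", "))
  }

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  filt <- fix[, "FILTER"]; filt[is.na(filt)] <- "."
  is_snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  is_multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  pass <- filt %in% keep_filter
  keep <- is_snp & pass          # multiallelic records fail nchar(alt)==1
  n_multi <- sum(is_multi & pass)
  n_nonsnp <- sum(!is_snp & !is_multi & pass)
  n_failed <- sum(!pass)

  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, samples$sample,
                                              drop = FALSE]
  parsed <- parse_gt_matrix(gt, samples$ploidy)
  n_hap_het <- 0L
  if (drop_haploid_hets && any(parsed$haploid_het_site)) {
    n_hap_het <- sum(parsed$haploid_het_site)
    sel <- !parsed$haploid_het_site
    parsed$alt <- parsed$alt[sel, , drop = FALSE]
    parsed$called <- parsed$called[sel, , drop = FALSE]
    keep[keep] <- sel
  }

  pops <- populations(samples)
  pop_of <- samples$population
  alt_mat <- sapply(pops, function(p)
    rowSums(parsed$alt[, pop_of == p, drop = FALSE]))
  called_mat <- sapply(pops, function(p)
    rowSums(parsed$called[, pop_of == p, drop = FALSE]))
  if (sum(keep) == 1L) {
    alt_mat <- matrix(alt_mat, 1, dimnames = list(NULL, pops))
    called_mat <- matrix(called_mat, 1, dimnames = list(NULL, pops))
  }
  if (sum(keep) == 0L) {
    alt_mat <- matrix(integer(), 0, length(pops), dimnames = list(NULL, pops))
    called_mat <- alt_mat
  }

  report <- tibble::tibble(
    filter = c("filter_failed", "multiallelic", "non_snp", "haploid_het",
               "retained"),
    n = c(n_failed, n_multi, n_nonsnp, n_hap_het, sum(keep))
  )
  site_counts(
    chrom = fix[keep, "CHROM"], pos = as.integer(fix[keep, "POS"]),
    ref = ref[keep], alt = alt[keep],
    alt_count = alt_mat, called_count = called_mat,
    chrom_lengths = contig_lengths_from_meta(vcf@meta),
    filter_report = report
  )
}

empty_filter_report <- function() {
  tibble::tibble(filter = c("filter_failed", "multiallelic", "non_snp",
                            "haploid_het", "retained"),
                 n = integer(5))
}

# Parse a character GT matrix (sites x samples) into per-sample alt and
# called allele counts, honoring per-sample ploidy.  Accepts "0", "1",
# "0/1", "0|1", "./.", ".", NA.  For ploidy-1 samples a diploid-style
# homozygous call counts one chromosome; a heterozygous call marks the
# site for removal (haploid_het_site).
parse_gt_matrix <- function(gt, ploidy) {
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  nsite <- nrow(gt); nsamp <- ncol(gt)
  codes <- unique(as.vector(gt))
  lut_alt <- numeric(0); lut_called <- numeric(0); lut_het <- logical(0)
  key <- character(0)
  for (g in codes) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) {
      a <- 0; n <- 0; h <- FALSE
    } else {
      al <- strsplit(g, "[/|]")[[1]]
      al <- al[al != ""]
      if (!all(al %in% c("0", "1", "."))) {
        stop("unparseable or non-biallelic GT: '", g, "'")
      }
      ok <- al != "."
      a <- sum(al[ok] == "1"); n <- sum(ok)
      h <- n == 2 && a == 1
    }
    key <- c(key, if (is.na(g)) "\r<NA>" else g)
    lut_alt <- c(lut_alt, a); lut_called <- c(lut_called, n)
    lut_het <- c(lut_het, h)
  }
  gt_key <- gt; gt_key[is.na(gt_key)] <- "\r<NA>"
  idx <- match(gt_key, key)
  alt <- matrix(lut_alt[idx], nsite, nsamp)
  called <- matrix(lut_called[idx], nsite, nsamp)
  het <- matrix(lut_het[idx], nsite, nsamp)

  hap <- which(ploidy == 1L)
  haploid_het_site <- if (length(hap)) {
    rowSums(het[, hap, drop = FALSE]) > 0
  } else rep(FALSE, nsite)
  # a haploid sample with a homozygous diploid-style call carries ONE
  # chromosome: halve its allele dose.  A heterozygous haploid call is
  # uninterpretable; if the site is not dropped wholesale the call is
  # treated as missing.
  if (length(hap)) {
    hh <- het[, hap, drop = FALSE]
    two <- called[, hap, drop = FALSE] == 2 & !hh
    called[, hap][two] <- 1
    alt[, hap][two] <- alt[, hap][two] / 2  # 0/0 -> 0, 1/1 -> 1
    called[, hap][hh] <- 0
    alt[, hap][hh] <- 0
  }
  list(alt = alt, called = called, haploid_het_site = haploid_het_site)
}

contig_lengths_from_meta <- function(meta) {
  m <- grep("^##contig=", meta, value = TRUE)
  if (!length(m)) return(NULL)
  id <- sub(".*ID=([^,>]+).*", "\\1", m)
  len <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", m)))
  if (all(is.na(len))) return(NULL)
  stats::setNames(len, id)
}

#' Allele frequencies per population
#' @param sites a `site_counts` object.
#' @return matrix (sites x populations) of alt-allele frequencies;
#'   NaN where a population has no called alleles.
#' @export
allele_freqs <- function(sites) sites$alt_count / sites$called_count

#' Write site counts back to a minimal VCF (GT-only)
#'
#' Used for round-trip checks and to export filtered or simulated site
#' sets.  Allele counts alone cannot be turned back into genotypes, so
#' this writer takes the per-sample genotype matrix.
#'
#' @param gt character genotype matrix (sites x samples).
#' @param chrom,pos,ref,alt site fields (`pos` 1-based).
#' @param sample_names column names for the genotype matrix.
#' @param path output path.
#' @param chrom_lengths optional named lengths written as contig lines.
#' @return `path`, invisibly.
#' @export
write_gt_vcf <- function(gt, chrom, pos, ref, alt, sample_names, path,
                         chrom_lengths = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(chrom_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
              as.integer(chrom_lengths))
    },
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  if (length(pos)) {
    body <- paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT",
                  sep = "\t")
    body <- paste(body, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  } else body <- character(0)
  writeLines(c(header, body), path)
  invisible(path)
}
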