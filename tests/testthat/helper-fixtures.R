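# In-code fixtures: tiny VCFs and sample tables written to tempfiles.

write_fixture_vcf <- function(records, sample_names, path = tempfile(fileext = ".vcf"),
                              contigs = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(contigs)) sprintf("##contig=<ID=%s,length=%d>",
                                   names(contigs), as.integer(contigs)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", sample_names), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gts, filter = "PASS") {
  paste(c(chrom, pos, ".", ref, alt, ".", filter, ".", "GT", gts),
        collapse = "\t")
}

fixture_samples <- function(pops = c(A = 2, B = 1), ploidy = NULL,
                            path = tempfile(fileext = ".tsv")) {
  # pops: named vector, number of samples per population
  ids <- unlist(lapply(names(pops), function(p)
    sprintf("%s_s%d", p, seq_len(pops[[p]]))))
  pop <- rep(names(pops), pops)
  if (is.null(ploidy)) ploidy <- rep(2L, length(ids))
  writeLines(c("sample\tpopulation\tploidy",
               sprintf("%s\t%s\t%d", ids, pop, ploidy)), path)
  path
}

# site_counts built directly from count matrices (bypassing VCF I/O)
counts_fixture <- function(chrom, pos, alt, called, pops = colnames(alt),
                           chrom_lengths = NULL) {
  colnames(alt) <- pops; colnames(called) <- pops
  site_counts(chrom, pos, rep("A", length(pos)), rep("G", length(pos)),
              alt, called, chrom_lengths = chrom_lengths)
}

# window table on a regular grid with given fst (and optional zfst)
window_fixture <- function(fst, width = 20000, chrom = "chr1",
                           chrom_lengths = NULL) {
  n <- length(fst)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- stats::setNames(n * width, chrom)
  }
  w <- make_windows(chrom_lengths, width)
  stopifnot(nrow(w) == n)
  out <- tibble::as_tibble(w[, c("chrom", "start", "end")])
  out$n_snps <- rep(50L, n)
  out$fst_p1_p2 <- fst
  attr(out, "chrom_lengths") <- chrom_lengths
  attr(out, "width") <- width
  out
}
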