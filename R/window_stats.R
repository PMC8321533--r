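#' Tile chromosomes into nonoverlapping windows
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param width window width in bp (default 20 kb).
#' @return A [region_set()] tiling each chromosome; the last window of a
#'   chromosome may be shorter than `width`.
#' @export
make_windows <- function(chrom_lengths, width = 20000) {
  stopifnot(!is.null(names(chrom_lengths)), width > 0)
  parts <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, max(L - 1, 0), by = width)
    tibble::tibble(chrom = ch, start = starts, end = pmin(starts + width, L))
  })
  out <- do.call(rbind, parts)
  region_set(out$chrom, out$start, out$end, chrom_lengths = chrom_lengths)
}

#' Windowed diversity and divergence statistics
#'
#' Computes, in nonoverlapping windows: nucleotide diversity per
#' population (`pi_<pop>`), absolute divergence (`dxy_<p1>_<p2>`) and
#' Hudson's FST (`fst_<p1>_<p2>`, ratio of averages) per population
#' pair.
#'
#' Per-base statistics divide the summed per-site values by the window
#' length (`denominator = "window_length"`, minus any masked bases),
#' which treats all unreported positions as monomorphic -- appropriate
#' for SNP-only VCFs.  `denominator = "n_sites"` divides by the number
#' of usable SNPs instead (per-SNP averages).
#'
#' Windows whose usable-site count for a given statistic falls below
#' `min_snps` report NA for that statistic.  FST is additionally NA when
#' the summed denominator is zero.
#'
#' @param sites a [site_counts()] object.
#' @param width window width in bp.
#' @param chrom_lengths named lengths; defaults to the lengths carried by
#'   `sites`, else the maximum observed position rounded up to `width`.
#' @param pairs list of 2-element character vectors of population labels;
#'   default all pairs in order of appearance.
#' @param denominator `"window_length"` or `"n_sites"`.
#' @param min_snps minimum usable sites per window and statistic
#'   (default 10).
#' @param mask optional [region_set()] of bases excluded from the
#'   per-base denominator (e.g. assembly gaps).
#' @return tibble: chrom, start, end, n_snps, then one column per
#'   statistic.
#' @export
window_stats <- function(sites, width = 20000, chrom_lengths = NULL,
                         pairs = NULL,
                         denominator = c("window_length", "n_sites"),
                         min_snps = 10, mask = NULL) {
  denominator <- match.arg(denominator)
  if (is.null(chrom_lengths)) chrom_lengths <- attr(sites, "chrom_lengths")
  if (is.null(chrom_lengths)) {
    mx <- tapply(sites$pos, sites$chrom, max)
    chrom_lengths <- stats::setNames(ceiling(as.numeric(mx) / width) * width,
                                     names(mx))
  }
  win <- make_windows(chrom_lengths, width)
  wkey <- paste0(win$chrom, ":", win$start)
  skey <- paste0(sites$chrom, ":", (sites$pos - 1) %/% width * width)
  sidx <- match(skey, wkey)
  if (anyNA(sidx)) stop("site position(s) beyond chromosome lengths")
  nwin <- nrow(win)
  pops <- sites$populations
  if (is.null(pairs)) {
    pairs <- utils::combn(pops, 2, simplify = FALSE)
  }

  out <- tibble::as_tibble(win[, c("chrom", "start", "end")])
  out$n_snps <- tab_sum(rep(1L, length(sidx)), sidx, nwin)

  base_len <- win$end - win$start
  if (!is.null(mask)) {
    base_len <- base_len - masked_bp_per_window(win, mask)
  }

  per_base <- function(total, usable) {
    den <- if (denominator == "window_length") base_len else usable
    val <- total / den
    val[usable < min_snps | den <= 0] <- NA_real_
    val
  }

  for (p in pops) {
    a <- sites$alt_count[, p]; n <- sites$called_count[, p]
    usable <- n >= 2
    pi_site <- site_pi(a, n)
    tot <- tab_sum(ifelse(usable, pi_site, 0), sidx, nwin)
    nus <- tab_sum(as.integer(usable), sidx, nwin)
    out[[paste0("pi_", p)]] <- per_base(tot, nus)
  }

  for (pr in pairs) {
    p1 <- pr[1]; p2 <- pr[2]
    a1 <- sites$alt_count[, p1]; n1 <- sites$called_count[, p1]
    a2 <- sites$alt_count[, p2]; n2 <- sites$called_count[, p2]
    f1 <- a1 / n1; f2 <- a2 / n2

    ok_d <- n1 >= 1 & n2 >= 1
    d_site <- site_dxy(f1, f2)
    tot_d <- tab_sum(ifelse(ok_d, d_site, 0), sidx, nwin)
    n_d <- tab_sum(as.integer(ok_d), sidx, nwin)
    out[[paste0("dxy_", p1, "_", p2)]] <- per_base(tot_d, n_d)

    cmp <- site_fst_components(a1, n1, a2, n2)
    ok_f <- n1 >= 2 & n2 >= 2 & !is.na(cmp$den) & cmp$den > 0
    num <- tab_sum(ifelse(ok_f, cmp$num, 0), sidx, nwin)
    den <- tab_sum(ifelse(ok_f, cmp$den, 0), sidx, nwin)
    n_f <- tab_sum(as.integer(ok_f), sidx, nwin)
    fst <- num / den
    fst[n_f < min_snps | den <= 0] <- NA_real_
    out[[paste0("fst_", p1, "_", p2)]] <- fst
  }
  attr(out, "chrom_lengths") <- chrom_lengths
  attr(out, "width") <- width
  out
}

# sum of x per group index (1..n), zeros for empty groups
tab_sum <- function(x, idx, n) {
  out <- numeric(n)
  if (length(x)) {
    s <- rowsum(as.numeric(x), idx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

masked_bp_per_window <- function(win, mask) {
  m <- merge_regions(mask)
  bp <- numeric(nrow(win))
  for (ch in unique(win$chrom)) {
    wi <- which(win$chrom == ch)
    ms <- m$start[m$chrom == ch]; me <- m$end[m$chrom == ch]
    if (!length(ms)) next
    lo <- outer(win$start[wi], ms, pmax); hi <- outer(win$end[wi], me, pmin)
    w <- hi - lo
    w[w < 0] <- 0
    bp[wi] <- rowSums(w)
  }
  bp
}

#' Standardize window FST to Z scores
#'
#' `ZFST = (window FST - median FST) / SD(FST)`, with the median and the
#' sample standard deviation taken over all non-NA windows genome-wide
#' for that comparison.  The non-NA ZFST vector therefore has median
#' exactly 0.  Negative FST values are retained; clamping them would
#' shift the median.
#'
#' @param fst numeric vector of window FST values (NA allowed).
#' @return numeric vector of the same length; NA windows stay NA.
#' @export
zfst <- function(fst) {
  ok <- !is.na(fst)
  if (sum(ok) < 2) stop("need at least 2 non-NA windows to standardize FST")
  s <- stats::sd(fst[ok])
  if (s == 0) stop("degenerate landscape: SD of FST is zero")
  (fst - stats::median(fst[ok])) / s
}

#' Add ZFST columns to a window table
#'
#' For every `fst_*` column present, appends the matching `zfst_*`
#' column.
#'
#' @param win window table from [window_stats()].
#' @return `win` with `zfst_*` columns appended.
#' @export
add_zfst <- function(win) {
  for (cn in grep("^fst_", names(win), value = TRUE)) {
    win[[sub("^fst_", "zfst_", cn)]] <- zfst(win[[cn]])
  }
  win
}

#' Window GC content from a FASTA
#'
#' Fraction of G+C among non-N bases in each window; NA where a window
#' is entirely N.
#'
#' @param win window table or region set.
#' @param fasta path to a FASTA file, or a `Biostrings::DNAStringSet`.
#' @return numeric vector, one value per row of `win`.
#' @export
gc_content <- function(win, fasta) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("gc_content requires the Biostrings package")
  }
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  out <- rep(NA_real_, nrow(win))
  for (ch in unique(win$chrom)) {
    if (!ch %in% names(seqs)) stop("chromosome absent from FASTA: ", ch)
    wi <- which(win$chrom == ch)
    if (any(win$end[wi] > length(seqs[[ch]]))) {
      stop("window beyond end of sequence ", ch)
    }
    v <- Biostrings::Views(seqs[[ch]], start = win$start[wi] + 1,
                           end = win$end[wi])
    counts <- Biostrings::letterFrequency(v, c("G", "C", "N"))
    informative <- (win$end[wi] - win$start[wi]) - counts[, "N"]
    gc <- (counts[, "G"] + counts[, "C"]) / informative
    gc[informative == 0] <- NA_real_
    out[wi] <- gc
  }
  out
}

#' Correlate two window-level statistics
#'
#' Pairwise-complete Spearman or Pearson correlation with its p-value,
#' e.g. between ZFST and recombination rate or between GC content and
#' recombination rate.
#'
#' @param x,y numeric vectors of equal length (NA pairs dropped).
#' @param method `"spearman"` or `"pearson"`.
#' @return list with `estimate`, `p.value`, `n`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    warning("constant input; correlation undefined")
    return(list(estimate = NA_real_, p.value = NA_real_, n = sum(ok)))
  }
  ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = method))
  list(estimate = unname(ct$estimate), p.value = ct$p.value, n = sum(ok))
}

#' Fraction of each window covered by a region set
#'
#' Attaches BED-derived covariates (repeat fraction, mappability proxy)
#' to a window table.
#'
#' @param win window table or region set.
#' @param regions a region set.
#' @return numeric vector of covered fractions, one per window.
#' @export
window_cover_fraction <- function(win, regions) {
  masked_bp_per_window(win, regions) / (win$end - win$start)
}
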