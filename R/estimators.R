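#' Per-site nucleotide diversity
#'
#' Unbiased per-site heterozygosity: the fraction of the `n(n-1)/2`
#' sample-chromosome pairs that differ, `2a(n-a) / (n(n-1))` for `a`
#' alternate alleles among `n` called chromosomes.
#'
#' @param a alternate-allele count(s).
#' @param n called chromosome count(s); sites with `n < 2` return NA.
#' @return numeric vector in \[0, 1\].
#' @export
site_pi <- function(a, n) {
  out <- 2 * a * (n - a) / (n * (n - 1))
  out[n < 2] <- NA_real_
  out
}

#' Per-site absolute divergence
#'
#' Probability that a chromosome drawn from population 1 and one from
#' population 2 differ: `p1(1-p2) + p2(1-p1)`.  No sample-size
#' correction is involved (cross-population pairs are always independent
#' draws).
#'
#' @param p1,p2 alternate-allele frequencies.
#' @return numeric vector in \[0, 1\].
#' @export
site_dxy <- function(p1, p2) p1 * (1 - p2) + p2 * (1 - p1)

#' Per-site components of Hudson's FST
#'
#' Hudson's (1992) two-population estimator in the Bhatia et al.
#' ratio-of-averages form: per site, the numerator estimates the
#' between-population variance `(p1-p2)^2` minus the within-population
#' sampling terms `p(1-p)/(n-1)`, the denominator is the between-
#' population heterozygosity `p1(1-p2) + p2(1-p1)`.  Window FST is
#' `sum(num)/sum(den)` over usable sites, never the mean of per-site
#' ratios.
#'
#' @param a1,n1,a2,n2 alt and called counts in each population; sites
#'   with `n < 2` in either population return NA components.
#' @return list with numeric vectors `num` and `den`.
#' @export
site_fst_components <- function(a1, n1, a2, n2) {
  p1 <- a1 / n1; p2 <- a2 / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  bad <- n1 < 2 | n2 < 2
  num[bad] <- NA_real_; den[bad] <- NA_real_
  list(num = num, den = den)
}
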