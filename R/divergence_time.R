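#' Harmonic number used by Watterson's estimator
#'
#' `a_n = sum_{i=1}^{n-1} 1/i`, the (n-1)th harmonic number for a sample
#' of `n` chromosomes.
#'
#' @param n number of sampled chromosomes (>= 2).
#' @return the harmonic number (vectorized over `n`).
#' @export
harmonic_a <- function(n) {
  if (any(n < 2)) stop("harmonic_a requires n >= 2")
  vapply(n, function(k) sum(1 / seq_len(k - 1)), numeric(1))
}

#' Watterson's theta per base
#'
#' `theta_w = K / (a_n * L)` for `K` segregating sites among `n`
#' chromosomes over `L` accessible bases.  With `L` equal to the total
#' assembly length this is the genome-wide per-base population mutation
#' rate.
#'
#' @param K number of segregating sites.
#' @param n number of sampled chromosomes.
#' @param L accessible bases.
#' @return per-base theta.
#' @export
watterson_theta <- function(K, n, L) {
  stopifnot(K >= 0, L > 0)
  K / (harmonic_a(n) * L)
}

#' Effective population size of a haplodiploid from theta
#'
#' Haplodiploids carry three autosome copies per breeding pair (two in
#' the diploid female, one in the haploid male), so the population
#' mutation rate is `theta = 3 Ne mu` and `Ne = theta / (3 mu)`.
#'
#' @param theta_w per-base Watterson's theta.
#' @param mu per-site per-generation mutation rate (default 3.6e-9, a
#'   direct pedigree estimate for bumblebees).
#' @return effective population size (individuals).
#' @export
ne_from_theta <- function(theta_w, mu = 3.6e-9) {
  stopifnot(mu > 0)
  theta_w / (3 * mu)
}

#' Estimate split time from window FST outside islands of divergence
#'
#' Windows overlapping IoDs are excluded (they do not reflect the
#' genome-wide divergence history), each remaining window FST is
#' transformed to drift units `T = -ln(1 - FST)`, and the mean `T` is
#' scaled to generations by `t = 3 Ne mean(T)` -- the haplodiploid
#' analogue of `T = t / 3Ne`.  At one generation per year, `t` is also
#' the split age in years.  The 95% confidence interval is a percentile
#' bootstrap over windows (resampled with replacement; the resampled
#' mean T is scaled by the same `3 Ne`).
#'
#' @param win window table with an `fst_*` column.
#' @param fst_col name of the FST column to use.
#' @param Ne effective size; a vector (e.g. the two species' estimates)
#'   is averaged arithmetically -- the model assumes the populations
#'   share one size, and the symmetric mean is the neutral default when
#'   their estimates differ.
#' @param islands optional region set of IoDs to exclude.
#' @param n_boot bootstrap replicates (default 5000).
#' @param conf confidence level (default 0.95).
#' @param seed optional seed for the bootstrap.
#' @return list of class `divtime`: `mean_T`, `t`, `ci_low`, `ci_high`,
#'   `Ne_used`, `n_windows`, `n_boot`, `n_excluded_island`,
#'   `n_excluded_na`, and `headline_T = -ln(1 - mean FST)` (always
#'   `<= mean_T` by Jensen's inequality; both are reported because the
#'   window-mean convention is the one used throughout).
#' @export
estimate_split_time <- function(win, fst_col, Ne, islands = NULL,
                                n_boot = 5000, conf = 0.95, seed = NULL) {
  fst <- win[[fst_col]]
  if (is.null(fst)) stop("no column ", fst_col)
  keep <- rep(TRUE, nrow(win))
  if (!is.null(islands) && nrow(islands) > 0) {
    keep <- classify_windows(win, islands) == "background"
  }
  n_island <- sum(!keep)
  usable <- keep & !is.na(fst) & fst < 1
  n_na <- sum(keep) - sum(usable)
  if (sum(usable) < 2) stop("fewer than 2 usable windows outside islands")
  Tw <- -log(1 - fst[usable])
  mean_T <- mean(Tw)
  headline_T <- -log(1 - mean(fst[usable]))
  stopifnot(mean_T >= headline_T - 1e-12)  # Jensen: convexity of -ln(1-x)
  Ne_used <- mean(Ne)
  t_hat <- 3 * Ne_used * mean_T
  if (!is.null(seed)) set.seed(seed)
  nw <- length(Tw)
  # resample in chunks to bound peak memory at ~2e7 doubles
  chunk <- max(1L, min(n_boot, as.integer(2e7 / nw)))
  boot_means <- numeric(n_boot)
  done <- 0L
  while (done < n_boot) {
    k <- min(chunk, n_boot - done)
    boot_means[done + seq_len(k)] <-
      colMeans(matrix(sample(Tw, nw * k, replace = TRUE), nrow = nw))
    done <- done + k
  }
  qs <- stats::quantile(3 * Ne_used * boot_means,
                        c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  structure(
    list(mean_T = mean_T, headline_T = headline_T, t = t_hat,
         ci_low = qs[1], ci_high = qs[2], conf = conf, Ne_used = Ne_used,
         n_windows = nw, n_boot = n_boot,
         n_excluded_island = n_island, n_excluded_na = n_na, seed = seed),
    class = "divtime"
  )
}

#' @export
print.divtime <- function(x, ...) {
  cat(sprintf(
    "<divtime> t = %.0f generations (%d%% CI %.0f-%.0f), mean T = %.4g, Ne = %.0f, %d windows, %d bootstrap reps\n",
    x$t, round(100 * x$conf), x$ci_low, x$ci_high, x$mean_T, x$Ne_used,
    x$n_windows, x$n_boot))
  invisible(x)
}
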