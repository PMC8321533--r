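#' Randomize region placement per chromosome
#'
#' Each region is re-placed uniformly on its own chromosome with its
#' size preserved: `start ~ Uniform{0, ..., L - len}`.  Randomized
#' regions may overlap one another (`allow_overlap = TRUE`, the
#' default); rejection sampling enforces disjoint placements otherwise.
#' Regions never move between chromosomes.
#'
#' @param regions a [region_set()] whose `chrom_lengths` attribute (or
#'   the `chrom_lengths` argument) covers every chromosome present.
#' @param chrom_lengths named lengths; defaults to the attribute on
#'   `regions`.
#' @param allow_overlap may randomized regions overlap each other?
#' @param max_tries rejection-sampling attempts per chromosome when
#'   `allow_overlap = FALSE`.
#' @return a `region_set` of identical sizes at random positions.  Uses
#'   the R RNG: seed with [set.seed()] for reproducibility.
#' @export
randomize_regions <- function(regions, chrom_lengths = NULL,
                              allow_overlap = TRUE, max_tries = 1000) {
  if (is.null(chrom_lengths)) chrom_lengths <- chrom_lengths_of(regions)
  if (is.null(chrom_lengths)) stop("chromosome lengths required")
  len <- regions$end - regions$start
  L <- chrom_lengths[regions$chrom]
  if (any(is.na(L))) stop("region chromosome missing from chrom_lengths")
  if (any(len > L)) stop("region longer than its chromosome")
  draw <- function(idx) {
    # uniform integer start in {0..L-len}; floor(runif) is safe because
    # runif() < 1 strictly
    pmin(floor(runif(length(idx)) * (L[idx] - len[idx] + 1)),
         L[idx] - len[idx])
  }
  start <- draw(seq_along(len))
  if (!allow_overlap) {
    for (ch in unique(regions$chrom)) {
      idx <- which(regions$chrom == ch)
      if (sum(len[idx]) > chrom_lengths[[ch]]) {
        stop("regions cannot be placed without overlap on ", ch)
      }
      tries <- 0
      while (has_self_overlap(start[idx], start[idx] + len[idx])) {
        start[idx] <- draw(idx)
        tries <- tries + 1
        if (tries > max_tries) {
          stop("could not place regions without overlap on ", ch)
        }
      }
    }
  }
  region_set(regions$chrom, start, start + len,
             chrom_lengths = chrom_lengths)
}

has_self_overlap <- function(s, e) {
  o <- order(s)
  any(s[o][-1] < cummax(e[o])[-length(e)])
}

#' Permutation test of region-set overlap
#'
#' Tests whether the observed overlap between two region sets exceeds
#' (or falls short of) the overlap expected when placements are random:
#' set A (or both sets) is re-placed per chromosome with sizes preserved
#' `n_perm` times, the overlap statistic is recomputed each time, and
#' the empirical p-value is `(#(null >= observed) + 1) / (n_perm + 1)`
#' for `alternative = "greater"` (`<=` for `"less"`).  The Z-score
#' `(observed - null_mean)/null_sd` and the fold enrichment
#' `observed/null_mean` summarize effect size.
#'
#' @param a,b region sets (A is the query of [overlap_stat()]).
#' @param chrom_lengths named chromosome lengths.
#' @param n_perm number of permutations (default 1000).
#' @param randomize `"A"` re-places only set A; `"both"` re-places both.
#' @param mode overlap statistic, see [overlap_stat()].
#' @param alternative `"greater"` (enrichment, default) or `"less"`.
#' @param seed optional integer seed recorded in the result.
#' @return list of class `perm_test`: `observed`, `null_mean`,
#'   `null_sd`, `z_score` (NA when `null_sd` is 0), `p_empirical`,
#'   `fold`, `n_perm`, `randomized`, `mode`, `alternative`, `seed`.
#' @export
perm_test <- function(a, b, chrom_lengths = NULL, n_perm = 1000,
                      randomize = c("A", "both"),
                      mode = c("n_query_overlapping", "bp_overlap"),
                      alternative = c("greater", "less"), seed = NULL) {
  randomize <- match.arg(randomize)
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  stopifnot(n_perm >= 1)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- chrom_lengths_of(a)
    if (is.null(chrom_lengths)) chrom_lengths <- chrom_lengths_of(b)
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- overlap_stat(a, b, mode)
  null <- perm_null_stats(a, b, chrom_lengths, n_perm, randomize, mode)
  null_mean <- mean(null); null_sd <- stats::sd(null)
  p <- if (alternative == "greater") {
    (sum(null >= obs) + 1) / (n_perm + 1)
  } else {
    (sum(null <= obs) + 1) / (n_perm + 1)
  }
  structure(
    list(observed = obs, null_mean = null_mean, null_sd = null_sd,
         z_score = if (null_sd > 0) (obs - null_mean) / null_sd else NA_real_,
         p_empirical = p,
         fold = if (null_mean > 0) obs / null_mean else NA_real_,
         n_perm = n_perm, randomized = randomize, mode = mode,
         alternative = alternative, seed = seed),
    class = "perm_test"
  )
}

# The permutation loop on plain vectors: semantically identical to
# randomize_regions() + overlap_stat() per iteration, but without
# tibble construction costs.  Uses the same uniform start law
# floor(runif * (L - len + 1)).
perm_null_stats <- function(a, b, chrom_lengths, n_perm, randomize,
                            mode) {
  chroms <- names(chrom_lengths)
  ai <- match(a$chrom, chroms); bi <- match(b$chrom, chroms)
  alen <- a$end - a$start; blen <- b$end - b$start
  aL <- chrom_lengths[ai]; bL <- chrom_lengths[bi]
  b_by <- split(seq_along(bi), bi)
  a_by <- split(seq_along(ai), ai)
  bs_fix <- b$start; be_fix <- b$end
  vapply(seq_len(n_perm), function(i) {
    as_ <- pmin(floor(runif(length(alen)) * (aL - alen + 1)), aL - alen)
    ae <- as_ + alen
    if (randomize == "both") {
      bs <- pmin(floor(runif(length(blen)) * (bL - blen + 1)), bL - blen)
      be <- bs + blen
    } else {
      bs <- bs_fix; be <- be_fix
    }
    total <- 0
    for (ch in names(a_by)) {
      ia <- a_by[[ch]]; ib <- b_by[[ch]]
      if (is.null(ib)) next
      if (mode == "n_query_overlapping") {
        u <- union_vec(bs[ib], be[ib])
        hit <- outer(as_[ia], u$e, `<`) & outer(ae[ia], u$s, `>`)
        total <- total + sum(rowSums(hit) > 0)
      } else {
        ua <- union_vec(as_[ia], ae[ia]); ub <- union_vec(bs[ib], be[ib])
        w <- outer(ua$e, ub$e, pmin) - outer(ua$s, ub$s, pmax)
        total <- total + sum(w[w > 0])
      }
    }
    total
  }, numeric(1))
}

# interval union on plain vectors
union_vec <- function(s, e) {
  if (length(s) == 1L) return(list(s = s, e = e))
  o <- order(s)
  s <- s[o]; e <- cummax(e[o])
  new <- c(TRUE, s[-1] > e[-length(e)])
  id <- cumsum(new)
  list(s = s[new], e = as.numeric(tapply(e, id, max)))
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> observed=%g null=%.3g+/-%.3g z=%.3g fold=%.3g p=%.4g (%s, %d perms, randomize %s)\n",
    x$observed, x$null_mean, x$null_sd,
    ifelse(is.na(x$z_score), NA, x$z_score), x$fold, x$p_empirical,
    x$mode, x$n_perm, x$randomized))
  invisible(x)
}
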