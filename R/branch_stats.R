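#' Transform FST to divergence-time units
#'
#' Under neutral divergence without migration, `FST = 1 - exp(-T)` with
#' `T` the split time in drift units, so `T = -ln(1 - FST)`.  Windows
#' with `FST = 1` have an undefined (infinite) branch and return NA with
#' a warning.  Slightly negative window FST maps to a small negative T
#' and is retained so that branch sums stay exact.
#'
#' @param fst numeric vector of window FST values.
#' @return numeric vector of `T` values.
#' @export
fst_to_T <- function(fst) {
  out <- -log(1 - fst)
  sat <- !is.na(fst) & fst >= 1
  if (any(sat)) {
    warning(sum(sat), " window(s) with FST >= 1: T undefined, set to NA")
    out[sat] <- NA_real_
  }
  out
}

#' Population branch statistic
#'
#' Branch length leading to focal population S1 on the (S1, S2, outgroup
#' S0) triplet: `PBS = (T_12 + T_10 - T_20) / 2`, where each `T` is the
#' divergence-time transform of the corresponding pairwise FST.
#' Swapping the roles of S1 and S2 swaps `T_10`/`T_20` and yields the S2
#' branch; the two in-group branches always sum to `T_12`.
#'
#' @param T_12 divergence-time units between the two in-group
#'   populations.
#' @param T_10 between S1 and the outgroup.
#' @param T_20 between S2 and the outgroup.
#' @return numeric vector of PBS values for S1 (NA wherever an input is
#'   NA).
#' @export
pbs <- function(T_12, T_10, T_20) (T_12 + T_10 - T_20) / 2

#' Append T and PBS columns for a population triplet
#'
#' @param win window table with `fst_*` columns.
#' @param pop1,pop2 the two in-group population labels.
#' @param outgroup the outgroup label.
#' @return `win` with columns `T_<pop1>_<pop2>`, `T_<pop1>_<outgroup>`,
#'   `T_<pop2>_<outgroup>`, `pbs_<pop1>`, `pbs_<pop2>` appended.
#' @export
add_pbs <- function(win, pop1, pop2, outgroup) {
  f12 <- fst_col(win, pop1, pop2)
  f10 <- fst_col(win, pop1, outgroup)
  f20 <- fst_col(win, pop2, outgroup)
  T12 <- fst_to_T(win[[f12]])
  T10 <- fst_to_T(win[[f10]])
  T20 <- fst_to_T(win[[f20]])
  win[[paste0("T_", pop1, "_", pop2)]] <- T12
  win[[paste0("T_", pop1, "_", outgroup)]] <- T10
  win[[paste0("T_", pop2, "_", outgroup)]] <- T20
  win[[paste0("pbs_", pop1)]] <- pbs(T12, T10, T20)
  win[[paste0("pbs_", pop2)]] <- pbs(T12, T20, T10)
  win
}

# locate the fst column for a pair regardless of label order
fst_col <- function(win, p1, p2) {
  cand <- c(paste0("fst_", p1, "_", p2), paste0("fst_", p2, "_", p1))
  hit <- cand[cand %in% names(win)]
  if (!length(hit)) stop("no FST column for pair ", p1, "/", p2)
  hit[1]
}
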