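#' Average window statistics by distance from island centers
#'
#' For each island, the window containing its midpoint (rounded down to
#' the window grid) is distance 0, and the windows at `center + k*step`
#' for `k = -max_dist/step ... +max_dist/step` contribute to the signed
#' distance bin `k*step` (clipped at chromosome ends).  Bin means pool
#' all islands; windows inside the neighborhoods of several islands
#' contribute to each (simple pooled mean).  With `pool = "absolute"`
#' the two directions are folded onto non-negative distances.
#'
#' @param win window table on a regular grid.
#' @param islands non-empty region set of IoDs.
#' @param stat_cols columns of `win` to profile.
#' @param max_dist maximum distance from center (default 5 Mb).
#' @param step bin width, must equal the window width (default 20 kb).
#' @param pool `"signed"` or `"absolute"`.
#' @return tibble: `distance` (bp), `n_<stat>` and `mean_<stat>` per
#'   statistic; attribute `genome_mean` holds the genome-wide mean of
#'   each statistic over all windows.
#' @export
island_profile <- function(win, islands, stat_cols, max_dist = 5e6,
                           step = 20000, pool = c("signed", "absolute")) {
  pool <- match.arg(pool)
  if (is.null(islands) || nrow(islands) == 0) stop("empty island set")
  kmax <- floor(max_dist / step)
  centers_chrom <- islands$chrom
  centers <- floor((islands$start + islands$end) / 2 / step) * step

  offsets <- seq(-kmax, kmax) * step
  grid <- expand.grid(island = seq_along(centers), off = offsets,
                      KEEP.OUT.ATTRS = FALSE)
  target_chrom <- centers_chrom[grid$island]
  target_start <- centers[grid$island] + grid$off

  wkey <- paste0(win$chrom, ":", win$start)
  idx <- match(paste0(target_chrom, ":", target_start), wkey)
  present <- !is.na(idx)  # clipped at chromosome ends

  dist <- grid$off[present]
  if (pool == "absolute") dist <- abs(dist)
  rows <- idx[present]

  out <- tibble::tibble(distance = sort(unique(
    if (pool == "absolute") abs(offsets) else offsets)))
  gm <- numeric(0)
  for (s in stat_cols) {
    v <- win[[s]][rows]
    ok <- !is.na(v)
    n <- tapply(ok, dist, sum)
    m <- tapply(ifelse(ok, v, 0), dist, sum) / n
    ord <- match(out$distance, as.numeric(names(n)))
    nn <- as.integer(n[ord]); nn[is.na(nn)] <- 0L
    mm <- as.numeric(m[ord]); mm[nn == 0L] <- NA_real_
    out[[paste0("n_", s)]] <- nn
    out[[paste0("mean_", s)]] <- mm
    gm[s] <- mean(win[[s]], na.rm = TRUE)
  }
  attr(out, "genome_mean") <- gm
  out
}

#' Distance at which a profile returns to the genome mean
#'
#' Starting from distance 0 and moving outward, the smallest absolute
#' distance whose bin mean crosses the genome-wide mean: for
#' `direction = "above"` the profile starts above the mean and the
#' crossing is the first bin at or below it; symmetrically for
#' `"below"`.  Signed profiles are folded to absolute distance first
#' (pooling both directions).
#'
#' @param profile result of [island_profile()] for a single statistic.
#' @param stat statistic name (the `mean_<stat>` column is used).
#' @param genome_mean reference level; defaults to the `genome_mean`
#'   attribute of the profile.
#' @param direction `"above"` or `"below"`: side on which the profile
#'   starts relative to the mean.
#' @return crossing distance in bp (0 if already at/across the mean at
#'   the center), or NA if the profile never returns to the mean.
#' @export
crossing_distance <- function(profile, stat, genome_mean = NULL,
                              direction = c("above", "below")) {
  direction <- match.arg(direction)
  if (is.null(genome_mean)) {
    genome_mean <- attr(profile, "genome_mean")[[stat]]
  }
  m <- profile[[paste0("mean_", stat)]]
  n <- profile[[paste0("n_", stat)]]
  d <- abs(profile$distance)
  ok <- !is.na(m) & n > 0
  # fold signed bins and order outward
  agg_m <- tapply(m[ok] * n[ok], d[ok], sum) / tapply(n[ok], d[ok], sum)
  dd <- as.numeric(names(agg_m))
  o <- order(dd)
  dd <- dd[o]; agg_m <- agg_m[o]
  crossed <- if (direction == "above") agg_m <= genome_mean
             else agg_m >= genome_mean
  if (!any(crossed)) return(NA_real_)
  dd[which(crossed)[1]]
}
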