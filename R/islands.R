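#' Parameters for island-of-divergence calling
#'
#' Defaults follow the threshold/merge/length rules used throughout the
#' package: windows with `ZFST >= 2` are highly divergent; flagged
#' windows within 60 kb (edge to edge) are merged into blocks; blocks
#' strictly longer than 100 kb are islands of divergence (IoDs);
#' optionally, retained IoDs within `second_merge_gap` (e.g. 1 Mb) are
#' merged, bridging short drops in ZFST inside one large divergent
#' region.
#'
#' @param z_threshold flagging threshold in SD units (inclusive).
#' @param merge_gap maximum edge-to-edge gap (bp) between flagged
#'   windows merged into one block.
#' @param min_length blocks must exceed this length (bp, strict) to be
#'   kept.
#' @param second_merge_gap optional second-pass merge distance (bp);
#'   `NULL` disables it.
#' @return list of class `island_params`.
#' @export
island_params <- function(z_threshold = 2, merge_gap = 60000,
                          min_length = 100000, second_merge_gap = NULL) {
  stopifnot(merge_gap >= 0, min_length >= 0,
            is.null(second_merge_gap) || second_merge_gap >= 0)
  structure(list(z_threshold = z_threshold, merge_gap = merge_gap,
                 min_length = min_length,
                 second_merge_gap = second_merge_gap),
            class = "island_params")
}

#' Flag highly divergent windows
#'
#' @param zfst numeric vector of ZFST values.
#' @param z_threshold inclusive threshold (default 2 SD units).
#' @return logical vector; NA windows are never flagged.
#' @export
call_divergent_windows <- function(zfst, z_threshold = 2) {
  !is.na(zfst) & zfst >= z_threshold
}

#' Merge flagged windows into islands of divergence
#'
#' @param win window table (chrom, start, end) sorted by position.
#' @param flagged logical vector from [call_divergent_windows()].
#' @param params an [island_params()] list.
#' @return [region_set()] of IoDs.  Lengths include any bridged
#'   non-flagged gaps; merging never crosses chromosomes.
#' @export
merge_and_filter <- function(win, flagged, params = island_params()) {
  stopifnot(length(flagged) == nrow(win))
  if (is.unsorted(order(win$chrom, win$start))) stop("windows must be sorted")
  fw <- win[flagged, , drop = FALSE]
  cl <- attr(win, "chrom_lengths")
  if (nrow(fw) == 0) {
    return(region_set(character(), numeric(), numeric(), chrom_lengths = cl))
  }
  blocks <- merge_regions(
    region_set(fw$chrom, fw$start, fw$end, chrom_lengths = cl),
    gap = params$merge_gap
  )
  iods <- blocks[blocks$end - blocks$start > params$min_length, ,
                 drop = FALSE]
  if (!is.null(params$second_merge_gap) && nrow(iods) > 1) {
    iods <- merge_regions(iods, gap = params$second_merge_gap)
  }
  iods
}

#' Call islands of divergence from a window table
#'
#' Convenience wrapper: flags windows on a `zfst_*` column and applies
#' [merge_and_filter()].
#'
#' @param win window table containing the given ZFST column.
#' @param zfst_col name of the ZFST column.
#' @param params an [island_params()] list.
#' @return [region_set()] of IoDs with a `summary` attribute (count,
#'   mean length, percent of genome when chromosome lengths are known).
#' @export
call_islands <- function(win, zfst_col, params = island_params()) {
  flagged <- call_divergent_windows(win[[zfst_col]], params$z_threshold)
  iods <- merge_and_filter(win, flagged, params)
  cl <- attr(win, "chrom_lengths")
  attr(iods, "summary") <- tibble::tibble(
    n_iods = nrow(iods),
    mean_length = if (nrow(iods)) mean(iods$end - iods$start) else NA_real_,
    total_bp = sum(iods$end - iods$start),
    pct_genome = if (!is.null(cl)) {
      100 * sum(iods$end - iods$start) / sum(cl)
    } else NA_real_
  )
  iods
}

#' Classify windows as island or background
#'
#' A window overlapping (>= 1 bp) any island is class `"IoD"`, otherwise
#' `"background"`.
#'
#' @param win window table.
#' @param islands a region set of IoDs.
#' @return character vector of classes, one per window.
#' @export
classify_windows <- function(win, islands) {
  cls <- rep("background", nrow(win))
  for (ch in unique(islands$chrom)) {
    wi <- which(win$chrom == ch)
    is_ <- islands$start[islands$chrom == ch]
    ie <- islands$end[islands$chrom == ch]
    if (!length(wi) || !length(is_)) next
    hit <- outer(win$start[wi], ie, `<`) & outer(win$end[wi], is_, `>`)
    cls[wi[rowSums(hit) > 0]] <- "IoD"
  }
  cls
}

#' Compare window statistics inside vs outside islands
#'
#' For each requested statistic: medians and means of the two classes,
#' the percent change of the mean inside relative to outside, and a
#' Wilcoxon rank-sum p-value.
#'
#' @param win window table.
#' @param islands region set of IoDs.
#' @param stats character vector of column names to compare.
#' @param alternative passed to [stats::wilcox.test()] (default
#'   two-sided).
#' @return tibble with one row per statistic: `stat`, `n_in`, `n_out`,
#'   `median_in`, `median_out`, `mean_in`, `mean_out`, `pct_change`,
#'   `p_value`.
#' @export
compare_inside_outside <- function(win, islands, stats,
                                   alternative = "two.sided") {
  cls <- classify_windows(win, islands)
  rows <- lapply(stats, function(s) {
    x_in <- win[[s]][cls == "IoD"]; x_in <- x_in[!is.na(x_in)]
    x_out <- win[[s]][cls == "background"]; x_out <- x_out[!is.na(x_out)]
    if (!length(x_in) || !length(x_out)) {
      return(tibble::tibble(stat = s, n_in = length(x_in),
                            n_out = length(x_out),
                            median_in = NA_real_, median_out = NA_real_,
                            mean_in = NA_real_, mean_out = NA_real_,
                            pct_change = NA_real_, p_value = NA_real_))
    }
    p <- suppressWarnings(
      stats::wilcox.test(x_in, x_out, alternative = alternative)$p.value
    )
    tibble::tibble(
      stat = s, n_in = length(x_in), n_out = length(x_out),
      median_in = stats::median(x_in), median_out = stats::median(x_out),
      mean_in = mean(x_in), mean_out = mean(x_out),
      pct_change = 100 * (mean(x_in) - mean(x_out)) / mean(x_out),
      p_value = p
    )
  })
  do.call(rbind, rows)
}
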