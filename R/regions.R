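#' Genomic region sets
#'
#' A region set is a tibble with columns `chrom`, `start`, `end` holding
#' 0-based half-open intervals, optionally carrying a named vector of
#' chromosome lengths as the `chrom_lengths` attribute.  VCF positions are
#' 1-based; all interval arithmetic inside the package is 0-based
#' half-open, and the conversion happens in exactly one place
#' ([read_sites()] keeps `pos` 1-based and window assignment subtracts 1).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param chrom_lengths optional named vector of chromosome lengths (bp).
#' @return A tibble of class `region_set`.
#' @examples
#' region_set(c("chr1", "chr1"), c(0, 50000), c(20000, 90000),
#'            chrom_lengths = c(chr1 = 1e6))
#' @export
region_set <- function(chrom, start, end, chrom_lengths = NULL) {
  if (length(chrom) == 1 && length(start) > 1) {
    chrom <- rep(chrom, length(start))
  }
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(end < start)) stop("region end < start")
  if (any(start < 0)) stop("negative region start")
  if (!is.null(chrom_lengths)) {
    if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
    bad <- !(chrom %in% names(chrom_lengths))
    if (any(bad)) stop("regions on chromosomes absent from chrom_lengths: ",
                       paste(unique(chrom[bad]), collapse = ", "))
    if (any(end > chrom_lengths[chrom])) stop("region end beyond chromosome length")
  }
  out <- tibble::tibble(chrom = as.character(chrom), start = start, end = end)
  out <- out[order(out$chrom, out$start, out$end), ]
  attr(out, "chrom_lengths") <- chrom_lengths
  class(out) <- c("region_set", class(out))
  out
}

#' @export
`[.region_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("chrom", "start", "end") %in% names(out))) {
    attr(out, "chrom_lengths") <- attr(x, "chrom_lengths")
    class(out) <- unique(c("region_set", class(out)))
  }
  out
}

chrom_lengths_of <- function(x) attr(x, "chrom_lengths")

#' Merge overlapping or near-adjacent intervals
#'
#' Collapses a region set into its union, optionally bridging gaps of at
#' most `gap` bp (edge-to-edge).  With `gap = 0` touching intervals
#' (`end == next start`) are still joined, matching half-open semantics.
#'
#' @param regions a [region_set()] or data frame with chrom/start/end.
#' @param gap maximum edge-to-edge distance (bp) to bridge; default 0.
#' @return A merged `region_set` (sorted, non-overlapping).
#' @export
merge_regions <- function(regions, gap = 0) {
  if (nrow(regions) == 0) {
    return(region_set(character(), numeric(), numeric(),
                      chrom_lengths_of(regions)))
  }
  r <- regions[order(regions$chrom, regions$start, regions$end), ]
  new_block <- c(TRUE, r$chrom[-1] != r$chrom[-nrow(r)] |
                   r$start[-1] > cummax_by(r$end, r$chrom)[-nrow(r)] + gap)
  id <- cumsum(new_block)
  region_set(
    chrom = r$chrom[new_block],
    start = r$start[new_block],
    end = as.numeric(tapply(r$end, id, max)),
    chrom_lengths = chrom_lengths_of(regions)
  )
}

# running maximum restarted at each chromosome change (input sorted by chrom)
cummax_by <- function(x, group) {
  out <- numeric(length(x))
  if (!length(x)) return(out)
  brk <- c(TRUE, group[-1] != group[-length(group)])
  gid <- cumsum(brk)
  for (g in unique(gid)) {
    i <- which(gid == g)
    out[i] <- cummax(x[i])
  }
  out
}

#' Total bp covered by a region set (after union)
#' @param regions a region set.
#' @return numeric, total covered bases.
#' @export
region_bp <- function(regions) {
  m <- merge_regions(regions)
  sum(m$end - m$start)
}

#' Overlap statistic between two region sets
#'
#' @param query,reference region sets on the same chromosome namespace.
#' @param mode `"n_query_overlapping"` counts query regions intersecting
#'   (>= 1 bp) at least one reference region; `"bp_overlap"` is the total
#'   bp of intersection between the unions of the two sets.
#' @return a single number.
#' @export
overlap_stat <- function(query, reference,
                         mode = c("n_query_overlapping", "bp_overlap")) {
  mode <- match.arg(mode)
  if (nrow(query) == 0 || nrow(reference) == 0) return(0)
  if (mode == "n_query_overlapping") {
    ref <- merge_regions(reference)
    n <- 0L
    for (ch in unique(query$chrom)) {
      qs <- query$start[query$chrom == ch]; qe <- query$end[query$chrom == ch]
      rs <- ref$start[ref$chrom == ch];     re <- ref$end[ref$chrom == ch]
      if (!length(rs)) next
      # query i overlaps some ref j iff qs < re and qe > rs for that j
      hit <- outer(qs, re, `<`) & outer(qe, rs, `>`)
      n <- n + sum(rowSums(hit) > 0L)
    }
    n
  } else {
    a <- merge_regions(query); b <- merge_regions(reference)
    bp <- 0
    for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
      as_ <- a$start[a$chrom == ch]; ae <- a$end[a$chrom == ch]
      bs <- b$start[b$chrom == ch];  be <- b$end[b$chrom == ch]
      lo <- outer(as_, bs, pmax); hi <- outer(ae, be, pmin)
      w <- hi - lo
      bp <- bp + sum(w[w > 0])
    }
    bp
  }
}

#' Read/write BED (0-based half-open, first three columns)
#' @param path file path.
#' @param chrom_lengths optional named lengths attached to the result.
#' @return a `region_set`.
#' @export
read_bed <- function(path, chrom_lengths = NULL) {
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  region_set(x[[1]], x[[2]], x[[3]], chrom_lengths = chrom_lengths)
}

#' @rdname read_bed
#' @param regions region set to write.
#' @export
write_bed <- function(regions, path) {
  df <- data.frame(regions$chrom, format(regions$start, scientific = FALSE, trim = TRUE),
                   format(regions$end, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chromosome-lengths table (chrom<TAB>length)
#' @param path two-column TSV without header, or with header chrom/length.
#' @return named numeric vector.
#' @export
read_chrom_lengths <- function(path) {
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (is.character(x[[2]])) { # header line present
    x <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  }
  stats::setNames(as.numeric(x[[2]]), x[[1]])
}
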