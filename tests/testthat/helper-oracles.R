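# Independent brute-force oracles.  These deliberately avoid the
# package's vectorized code paths: statistics are computed by explicit
# enumeration of chromosome pairs / interval positions.

# fraction of differing pairs among n chromosomes with a alt alleles
oracle_pi <- function(a, n) {
  alleles <- c(rep(1, a), rep(0, n - a))
  diff <- 0; tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    if (alleles[i] != alleles[j]) diff <- diff + 1
  }
  diff / tot
}

# fraction of differing cross-population pairs
oracle_dxy <- function(a1, n1, a2, n2) {
  x <- c(rep(1, a1), rep(0, n1 - a1))
  y <- c(rep(1, a2), rep(0, n2 - a2))
  diff <- 0
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    if (x[i] != y[j]) diff <- diff + 1
  }
  diff / (n1 * n2)
}

# Hudson (1992) per-site components, written out from the published
# formulas independently of site_fst_components()
oracle_hudson <- function(a1, n1, a2, n2) {
  p1 <- a1 / n1; p2 <- a2 / n2
  num <- (p1 - p2)^2 -
    p1 * (1 - p1) / (n1 - 1) -
    p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  c(num = unname(num), den = unname(den))
}

# per-window stats by an explicit per-site loop over a site_counts
# object; denominator = window length
oracle_window_stats <- function(sc, width, chrom_lengths, min_snps = 0) {
  win <- make_windows(chrom_lengths, width)
  pops <- sc$populations
  out <- as.data.frame(win[, c("chrom", "start", "end")])
  for (p in pops) out[[paste0("pi_", p)]] <- NA_real_
  out$dxy <- NA_real_; out$fst <- NA_real_
  for (w in seq_len(nrow(win))) {
    idx <- which(sc$chrom == win$chrom[w] &
                   sc$pos - 1 >= win$start[w] & sc$pos - 1 < win$end[w])
    L <- win$end[w] - win$start[w]
    for (p in pops) {
      s <- 0; used <- 0
      for (i in idx) {
        n <- sc$called_count[i, p]; a <- sc$alt_count[i, p]
        if (n >= 2) { s <- s + oracle_pi(a, n); used <- used + 1 }
      }
      out[[paste0("pi_", p)]][w] <- if (used >= min_snps) s / L else NA
    }
    sd_ <- 0; used_d <- 0; num <- 0; den <- 0; used_f <- 0
    for (i in idx) {
      a1 <- sc$alt_count[i, pops[1]]; n1 <- sc$called_count[i, pops[1]]
      a2 <- sc$alt_count[i, pops[2]]; n2 <- sc$called_count[i, pops[2]]
      if (n1 >= 1 && n2 >= 1) {
        sd_ <- sd_ + oracle_dxy(a1, n1, a2, n2); used_d <- used_d + 1
      }
      if (n1 >= 2 && n2 >= 2) {
        h <- oracle_hudson(a1, n1, a2, n2)
        if (h["den"] > 0) {
          num <- num + h["num"]; den <- den + h["den"]
          used_f <- used_f + 1
        }
      }
    }
    out$dxy[w] <- if (used_d >= min_snps) sd_ / L else NA
    out$fst[w] <- if (used_f >= min_snps && used_f > 0 && den > 0)
      num / den else NA
  }
  out
}

# interval union with gap bridging by position-set enumeration: mark
# every bp covered (coarse grid ok for window-aligned fixtures)
oracle_merge <- function(starts, ends, gap) {
  if (!length(starts)) return(data.frame(start = numeric(), end = numeric()))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  rs <- starts[1]; re <- ends[1]
  out <- NULL
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - re <= gap) {
      re <- max(re, ends[i])
    } else {
      out <- rbind(out, c(rs, re)); rs <- starts[i]; re <- ends[i]
    }
  }
  out <- rbind(out, c(rs, re))
  data.frame(start = out[, 1], end = out[, 2])
}

# O(nq * nr) overlap count
oracle_overlap_count <- function(q, r) {
  n <- 0
  for (i in seq_len(nrow(q))) {
    hit <- FALSE
    for (j in seq_len(nrow(r))) {
      if (q$chrom[i] == r$chrom[j] &&
          q$start[i] < r$end[j] && q$end[i] > r$start[j]) hit <- TRUE
    }
    if (hit) n <- n + 1
  }
  n
}

# random region set on given chromosomes
random_regions <- function(n, chrom_lengths, min_len = 1, max_len = NULL) {
  ch <- sample(names(chrom_lengths), n, replace = TRUE)
  L <- chrom_lengths[ch]
  if (is.null(max_len)) max_len <- pmax(min_len, floor(L / 4))
  len <- pmin(L, floor(runif(n, min_len, max_len)))
  st <- floor(runif(n) * (L - len + 1))
  region_set(ch, st, st + len, chrom_lengths = chrom_lengths)
}
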