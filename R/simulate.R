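#' Parameters for the two/three-population divergence simulator
#'
#' The generator emulates a pair of populations that split `t`
#' generations ago, with window-specific regimes:
#'
#' * `barrier` windows: no post-split homogenization (effective split
#'   time `t_eff = t`) and locally reduced diversity (`lambda < 1`,
#'   mimicking linked selection in low-recombination, often
#'   centromere-proximal regions).  These emulate barrier regions where
#'   gene flow was blocked.
#' * `background` windows: partial homogenization by gene flow,
#'   modelled as an effective-time reduction `t_eff = t (1 - g)`, with
#'   full diversity (`lambda = 1`).
#' * `lowrec_background` windows: gene flow as background but
#'   `lambda < 1` -- regions of low recombination without any barrier,
#'   the regime that produces "incidental" islands in allopatric
#'   comparisons.
#'
#' Per window the expected fixation index is
#' `F_exp = 1 - exp(-t_eff / (3 Ne lambda))` (haplodiploid drift clock;
#' `lambda` scales the local effective size).  Ancestral polymorphic
#' sites are placed at density `theta_anc * lambda` per base with
#' frequencies from a neutral-SFS-like 1/p grid; daughter frequencies
#' are Balding-Nichols beta draws around the ancestral frequency with
#' fixation index `F_exp`.  Post-split mutations are injected as fixed
#' differences at rate `2 mu t_eff` per base, so
#' `E[dXY] ~ theta_anc * lambda * hbar + 2 mu t_eff` with `hbar` the
#' mean per-site heterozygosity of the SFS grid.
#'
#' Defaults are chosen to mirror the empirical regimes at desk scale:
#' `Ne = 1000` with `mode = "sympatric"` gives background F around 0.21
#' and barrier F around 0.93 (the two modes of the bimodal sympatric
#' FST landscape), `mode = "allopatric"` gives background F around 0.12
#' with elevated-F low-recombination windows, and `mode = "neutral"` a
#' homogeneous landscape with F around 0.34.  `mu` is scaled up in the
#' same proportion as `Ne` is scaled down from the empirical values, so
#' the per-base mutation input `2 mu t` -- and with it the direction and
#' relative size of the dXY contrasts -- is preserved.
#'
#' @param mode `"sympatric"`, `"allopatric"`, or `"neutral"`; presets
#'   `t`, `g`, `lambda` and the window-class layout.
#' @param chrom_lengths named chromosome lengths (default three 4-Mb
#'   chromosomes).
#' @param width window width (default 20 kb).
#' @param Ne daughter/ancestral effective size (default 1000).
#' @param t split time in generations; mode default.
#' @param g gene-flow homogenization in \[0, 1) for non-barrier
#'   windows; mode default.
#' @param lambda diversity factor in (0, 1\] for barrier/lowrec windows;
#'   default 0.2.
#' @param mu per-site per-generation mutation rate driving post-split
#'   fixed differences; mode default (3.4e-7 desk-scaled for
#'   sympatric/allopatric, 0 for neutral).
#' @param theta_anc ancestral polymorphic-site density per base
#'   (default 0.003, about 60 SNPs per 20-kb window).
#' @param block_windows consecutive windows per special block (default
#'   20, i.e. 400-kb blocks).
#' @param blocks_per_chrom special blocks per chromosome (default 1,
#'   centered; the large single-IoD-per-chromosome pattern).
#' @param samples a [sample_table()]; default two populations, one of
#'   20 diploid females, one of 16 haploid males plus 2 diploid females.
#' @param outgroup simulate a third outgroup population (`og`, 10
#'   haploids) split `outgroup_factor * t` generations ago with no gene
#'   flow.
#' @param outgroup_factor multiplier for the outgroup split time
#'   (default 4).
#' @param n_grid ancestral-SFS grid resolution (default 100).
#' @return list of class `sim_params`; element `truth` is the
#'   per-window tibble (chrom, start, end, class, lambda, t_eff, F_exp).
#' @export
sim_params <- function(mode = c("sympatric", "allopatric", "neutral"),
                       chrom_lengths = c(chr1 = 4e6, chr2 = 4e6,
                                         chr3 = 4e6),
                       width = 20000, Ne = 1000, t = NULL, g = NULL,
                       lambda = 0.2, mu = NULL, theta_anc = 0.003,
                       block_windows = 20, blocks_per_chrom = 1,
                       samples = NULL, outgroup = FALSE,
                       outgroup_factor = 4, n_grid = 100) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    # drift components: background F ~ 0.21, barrier F ~ 0.93
    sympatric = list(t = 1595, g = 0.5566, mu = 3.4e-7,
                     special = "barrier"),
    # background F ~ 0.12, lowrec F ~ 0.47, no gene flow anywhere
    allopatric = list(t = 383, g = 0, mu = 3.4e-7,
                      special = "lowrec_background"),
    # homogeneous pure-drift landscape, F ~ 0.34: the regime assumed by
    # the split-time estimator (no post-split mutation input)
    neutral = list(t = 1246, g = 0, mu = 0, special = NULL)
  )
  if (is.null(t)) t <- defaults$t
  if (is.null(g)) g <- defaults$g
  if (is.null(mu)) mu <- defaults$mu
  stopifnot(g >= 0, g < 1, lambda > 0, lambda <= 1, mu >= 0, t >= 0)
  if (is.null(samples)) {
    samples <- sample_table(
      sample = c(sprintf("p1_w%02d", 1:20), sprintf("p2_d%02d", 1:16),
                 sprintf("p2_w%02d", 1:2)),
      population = c(rep("pop1", 20), rep("pop2", 18)),
      ploidy = c(rep(2L, 20), rep(1L, 16), rep(2L, 2))
    )
  }
  if (outgroup && !"og" %in% samples$population) {
    og <- sample_table(sprintf("og_d%02d", 1:10), rep("og", 10),
                       rep(1L, 10))
    samples <- sample_table(c(samples$sample, og$sample),
                            c(samples$population, og$population),
                            c(samples$ploidy, og$ploidy))
  }

  win <- make_windows(chrom_lengths, width)
  cls <- rep("background", nrow(win))
  if (!is.null(defaults$special)) {
    for (ch in names(chrom_lengths)) {
      wi <- which(win$chrom == ch)
      nw <- length(wi)
      for (b in seq_len(blocks_per_chrom)) {
        # blocks evenly spaced along the chromosome
        mid <- round(nw * b / (blocks_per_chrom + 1))
        lo <- max(1, mid - floor(block_windows / 2) + 1)
        hi <- min(nw, lo + block_windows - 1)
        cls[wi[lo:hi]] <- defaults$special
      }
    }
  }
  lam <- ifelse(cls == "background", 1, lambda)
  t_eff <- ifelse(cls == "barrier", t, t * (1 - g))
  F_exp <- 1 - exp(-t_eff / (3 * Ne * lam))
  truth <- tibble::tibble(chrom = win$chrom, start = win$start,
                          end = win$end, class = cls, lambda = lam,
                          t_eff = t_eff, F_exp = F_exp)
  structure(
    list(mode = mode, chrom_lengths = chrom_lengths, width = width,
         Ne = Ne, t = t, g = g, lambda = lambda, mu = mu,
         theta_anc = theta_anc, samples = samples, outgroup = outgroup,
         outgroup_factor = outgroup_factor, n_grid = n_grid,
         truth = truth),
    class = "sim_params"
  )
}

# discretized neutral SFS: frequencies k/(2N) for k = 1..2N-1, weight 1/k
sfs_grid <- function(n_grid) {
  k <- seq_len(2 * n_grid - 1)
  list(p = k / (2 * n_grid), w = (1 / k) / sum(1 / k))
}

# Balding-Nichols draw: beta around ancestral p with fixation index F
rbn <- function(p, F) {
  out <- p
  pos <- F > 0 & p > 0 & p < 1
  if (any(pos)) {
    shape <- (1 - F[pos]) / F[pos]
    out[pos] <- stats::rbeta(sum(pos), p[pos] * shape,
                             (1 - p[pos]) * shape)
  }
  out
}

#' Simulate per-site population allele frequencies
#'
#' Draws the ancestral polymorphic sites and post-split fixed
#' differences for every window of `params` and returns population
#' allele frequencies plus the per-window truth table.  Uses the R RNG
#' (seed with [set.seed()]).
#'
#' @param params a [sim_params()] object.
#' @return list: `sites` tibble (chrom, pos 1-based, origin
#'   "ancestral"/"new"), `freq` matrix (sites x populations), `truth`
#'   per-window tibble.
#' @export
simulate_frequencies <- function(params) {
  truth <- params$truth
  grid <- sfs_grid(params$n_grid)
  pops <- populations(params$samples)
  core <- setdiff(pops, "og")
  stopifnot(length(core) == 2)

  F_og <- 1 - exp(-params$outgroup_factor * params$t / (3 * params$Ne))
  acc_chrom <- list(); acc_pos <- list(); acc_orig <- list()
  acc_freq <- list()

  for (i in seq_len(nrow(truth))) {
    L <- truth$end[i] - truth$start[i]
    n_anc <- stats::rpois(1, params$theta_anc * truth$lambda[i] * L)
    n_new <- stats::rpois(1, 2 * params$mu * truth$t_eff[i] * L)
    n_tot <- n_anc + n_new
    if (n_tot == 0) next
    pos <- truth$start[i] + sample.int(L, n_tot)  # 1-based within window
    fm <- matrix(0, n_tot, length(pops), dimnames = list(NULL, pops))
    if (n_anc > 0) {
      p_anc <- sample(grid$p, n_anc, replace = TRUE, prob = grid$w)
      Fw <- rep(truth$F_exp[i], n_anc)
      fm[seq_len(n_anc), core[1]] <- rbn(p_anc, Fw)
      fm[seq_len(n_anc), core[2]] <- rbn(p_anc, Fw)
      if ("og" %in% pops) {
        fm[seq_len(n_anc), "og"] <- rbn(p_anc, rep(F_og, n_anc))
      }
    }
    if (n_new > 0) {
      # new mutations fixed in one daughter, absent elsewhere
      which_pop <- sample(core, n_new, replace = TRUE)
      rows <- n_anc + seq_len(n_new)
      fm[cbind(rows, match(which_pop, pops))] <- 1
    }
    acc_chrom[[length(acc_chrom) + 1L]] <- rep(truth$chrom[i], n_tot)
    acc_pos[[length(acc_pos) + 1L]] <- pos
    acc_orig[[length(acc_orig) + 1L]] <-
      rep(c("ancestral", "new"), c(n_anc, n_new))
    acc_freq[[length(acc_freq) + 1L]] <- fm
  }
  if ("og" %in% pops && params$outgroup) {
    # outgroup-specific fixed differences, uniform across the genome
    n_og <- stats::rpois(1, 2 * params$mu * params$outgroup_factor *
                           params$t * sum(params$chrom_lengths))
    if (n_og > 0) {
      ch <- sample(names(params$chrom_lengths), n_og, replace = TRUE,
                   prob = params$chrom_lengths)
      pos <- floor(runif(n_og) * params$chrom_lengths[ch]) + 1
      fm <- matrix(0, n_og, length(pops), dimnames = list(NULL, pops))
      fm[, "og"] <- 1
      acc_chrom[[length(acc_chrom) + 1L]] <- ch
      acc_pos[[length(acc_pos) + 1L]] <- pos
      acc_orig[[length(acc_orig) + 1L]] <- rep("new", n_og)
      acc_freq[[length(acc_freq) + 1L]] <- fm
    }
  }
  chroms <- as.character(unlist(acc_chrom))
  positions <- as.numeric(unlist(acc_pos))
  origin <- as.character(unlist(acc_orig))
  freq <- do.call(rbind, c(acc_freq,
                           list(matrix(numeric(0), 0, length(pops),
                                       dimnames = list(NULL, pops)))))
  dup <- duplicated(paste0(chroms, ":", positions))
  if (any(dup)) {  # rare collisions from outgroup-specific sites
    chroms <- chroms[!dup]; positions <- positions[!dup]
    origin <- origin[!dup]; freq <- freq[!dup, , drop = FALSE]
  }
  o <- order(chroms, positions)
  list(
    sites = tibble::tibble(chrom = chroms[o],
                           pos = as.integer(positions[o]),
                           origin = origin[o]),
    freq = freq[o, , drop = FALSE],
    truth = truth
  )
}

#' Sample mixed-ploidy genotypes from population frequencies
#'
#' Diploids are Hardy-Weinberg binomial(2, p) draws; haploids are
#' Bernoulli(p) and can never be heterozygous.
#'
#' @param freq matrix (sites x populations) of alt-allele frequencies.
#' @param samples a [sample_table()].
#' @return character genotype matrix (sites x samples): `"0/0"`,
#'   `"0/1"`, `"1/1"` for diploids; `"0"`, `"1"` for haploids.
#' @export
sample_genotypes <- function(freq, samples) {
  nsite <- nrow(freq)
  gt <- matrix("", nsite, nrow(samples),
               dimnames = list(NULL, samples$sample))
  dip_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(samples))) {
    p <- freq[, samples$population[j]]
    if (samples$ploidy[j] == 2L) {
      gt[, j] <- dip_codes[stats::rbinom(nsite, 2, p) + 1L]
    } else {
      gt[, j] <- as.character(stats::rbinom(nsite, 1, p))
    }
  }
  gt
}

#' Sample population allele counts directly from frequencies
#'
#' Equivalent to [sample_genotypes()] followed by per-population
#' counting when samples are in Hardy-Weinberg proportions (a binomial
#' over `n` chromosomes is the sum of the per-sample draws), but orders
#' of magnitude faster.  Used for moment checks and parameter-recovery
#' experiments at large site counts.
#'
#' @param freq matrix (sites x populations) of alt-allele frequencies.
#' @param n_chrom named vector of sampled chromosomes per population
#'   (e.g. from [n_chromosomes()]).
#' @param sites tibble with `chrom` and `pos` for the rows of `freq`.
#' @param chrom_lengths optional named lengths attached to the result.
#' @return a [site_counts()] object.
#' @export
sample_site_counts <- function(freq, n_chrom, sites,
                               chrom_lengths = NULL) {
  pops <- colnames(freq)
  stopifnot(all(pops %in% names(n_chrom)))
  nsite <- nrow(freq)
  alt <- sapply(pops, function(p)
    stats::rbinom(nsite, n_chrom[[p]], freq[, p]))
  called <- sapply(pops, function(p) rep(n_chrom[[p]], nsite))
  if (nsite == 1L) {
    alt <- matrix(alt, 1, dimnames = list(NULL, pops))
    called <- matrix(called, 1, dimnames = list(NULL, pops))
  }
  site_counts(sites$chrom, sites$pos, rep("A", nsite), rep("G", nsite),
              alt_count = alt, called_count = called,
              chrom_lengths = chrom_lengths)
}

#' Simulate a full dataset and write its artifacts
#'
#' Runs [simulate_frequencies()] and [sample_genotypes()] under a seed,
#' then writes a VCF, the sample table TSV, a truth BED of the special
#' (barrier / low-recombination) windows, a chromosome-lengths TSV and
#' a params JSON into `dir`.
#'
#' @param params a [sim_params()] object.
#' @param dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param seed integer seed; all randomness flows from it.
#' @return list: `sites`, `freq`, `truth`, `gt`, `samples`, `paths`
#'   (named file paths or NULL).
#' @export
simulate_dataset <- function(params, dir = NULL, seed = 1) {
  set.seed(seed)
  sim <- simulate_frequencies(params)
  gt <- sample_genotypes(sim$freq, params$samples)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      vcf = file.path(dir, "sim.vcf"),
      samples = file.path(dir, "samples.tsv"),
      truth_bed = file.path(dir, "truth.bed"),
      chrom_lengths = file.path(dir, "chrom_lengths.tsv"),
      params = file.path(dir, "params.json")
    )
    # alternating REF/ALT keeps alleles syntactically valid; identities
    # carry no information in the model
    nsite <- nrow(sim$sites)
    write_gt_vcf(gt, sim$sites$chrom, sim$sites$pos,
                 rep(c("A", "C"), length.out = nsite),
                 rep(c("G", "T"), length.out = nsite),
                 params$samples$sample, paths$vcf,
                 chrom_lengths = params$chrom_lengths)
    utils::write.table(params$samples, paths$samples, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    special <- sim$truth[sim$truth$class != "background", , drop = FALSE]
    write_bed(merge_regions(region_set(special$chrom, special$start,
                                       special$end)), paths$truth_bed)
    utils::write.table(
      data.frame(chrom = names(params$chrom_lengths),
                 length = as.integer(params$chrom_lengths)),
      paths$chrom_lengths, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      c(params[c("mode", "width", "Ne", "t", "g", "lambda", "mu",
                 "theta_anc", "outgroup", "outgroup_factor", "n_grid")],
        list(seed = seed, chrom_lengths = as.list(params$chrom_lengths))),
      paths$params, auto_unbox = TRUE, digits = NA)
  }
  list(sites = sim$sites, freq = sim$freq, truth = sim$truth, gt = gt,
       samples = params$samples, chrom_lengths = params$chrom_lengths,
       paths = paths)
}

#' Site counts directly from simulated truth (no VCF round trip)
#'
#' Convenience for tests and calibration experiments: converts a
#' simulated genotype matrix into [site_counts()] without touching the
#' filesystem.
#'
#' @param simdata result of [simulate_dataset()].
#' @return a [site_counts()] object.
#' @export
sim_site_counts <- function(simdata) {
  parsed <- parse_gt_matrix(simdata$gt, simdata$samples$ploidy)
  pops <- populations(simdata$samples)
  pop_of <- simdata$samples$population
  alt <- sapply(pops, function(p)
    rowSums(parsed$alt[, pop_of == p, drop = FALSE]))
  called <- sapply(pops, function(p)
    rowSums(parsed$called[, pop_of == p, drop = FALSE]))
  if (nrow(simdata$gt) == 1L) {
    alt <- matrix(alt, 1, dimnames = list(NULL, pops))
    called <- matrix(called, 1, dimnames = list(NULL, pops))
  }
  site_counts(simdata$sites$chrom, simdata$sites$pos,
              ref = rep("A", nrow(simdata$gt)),
              alt = rep("G", nrow(simdata$gt)),
              alt_count = alt, called_count = called,
              chrom_lengths = simdata$chrom_lengths)
}
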