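#' Run the full divergence-landscape pipeline from a configuration
#'
#' Executes, in order: site loading (VCF -> allele counts with the
#' mixed-ploidy filters), window statistics, ZFST standardization,
#' optional branch statistics against an outgroup, island calling,
#' inside/outside contrasts, optional region-overlap permutation tests
#' against a supplied repeat/feature BED, split-time estimation, and
#' island-center profiles.  All outputs are plain TSV/BED/JSON under
#' `config$out_dir`, plus a run manifest with seeds, parameters, stage
#' counts and output checksums.
#'
#' @param config a list (or path to a JSON file) with elements:
#'   `vcf`, `samples` (TSV path), `out_dir`; optional `chrom_lengths`
#'   (TSV path; default VCF contigs), `fasta`, `width` (20000),
#'   `min_snps` (10), `denominator`, `pairs` (list of 2-vectors;
#'   default all), `outgroup` (label), `islands` (list of
#'   [island_params()] arguments), `permutation_bed`, `n_perm` (1000),
#'   `mu` (3.6e-9), `n_boot` (5000), `profile_max_dist` (5e6),
#'   `seed` (1).
#' @return list with the main in-memory results (`windows`, `islands`,
#'   `contrasts`, `divtime`, `profiles`, `perm`, `manifest`),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  need <- c("vcf", "samples", "out_dir")
  if (!all(need %in% names(config))) {
    stop("config requires: ", paste(need, collapse = ", "))
  }
  cfg <- utils::modifyList(
    list(width = 20000, min_snps = 10, denominator = "window_length",
         n_perm = 1000, mu = 3.6e-9, n_boot = 5000,
         profile_max_dist = 5e6, seed = 1, islands = list()),
    config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)

  samples <- load_sample_table(cfg$samples)
  chrom_lengths <- if (!is.null(cfg$chrom_lengths)) {
    read_chrom_lengths(cfg$chrom_lengths)
  } else NULL
  pairs <- cfg$pairs
  if (!is.null(pairs) && !is.list(pairs)) pairs <- list(pairs)
  if (!is.null(pairs)) {
    known <- populations(samples)
    for (pr in pairs) {
      if (!all(pr %in% known)) stop("unknown population in pairs: ",
                                    paste(setdiff(pr, known), collapse = ", "))
    }
  }
  if (!is.null(cfg$outgroup) && !cfg$outgroup %in% populations(samples)) {
    stop("unknown outgroup population: ", cfg$outgroup)
  }

  sites <- read_sites(cfg$vcf, samples)
  if (is.null(chrom_lengths)) chrom_lengths <- attr(sites, "chrom_lengths")
  utils::write.table(attr(sites, "filter_report"),
                     file.path(cfg$out_dir, "site_filters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  win <- window_stats(sites, width = cfg$width,
                      chrom_lengths = chrom_lengths, pairs = pairs,
                      denominator = cfg$denominator,
                      min_snps = cfg$min_snps)
  win <- add_zfst(win)
  if (!is.null(cfg$fasta)) win$gc <- gc_content(win, cfg$fasta)
  if (is.null(pairs)) {
    pairs <- utils::combn(sites$populations, 2, simplify = FALSE)
  }
  core_pairs <- Filter(function(pr) is.null(cfg$outgroup) ||
                         !cfg$outgroup %in% pr, pairs)
  if (!is.null(cfg$outgroup)) {
    for (pr in core_pairs) win <- add_pbs(win, pr[1], pr[2], cfg$outgroup)
  }
  write_tsv_file(win, file.path(cfg$out_dir, "windows.tsv"))

  ipar <- do.call(island_params, cfg$islands)
  islands <- list(); contrasts <- list(); divtimes <- list()
  profiles <- list()
  for (pr in core_pairs) {
    tag <- paste0(pr[1], "_", pr[2])
    zc <- paste0("zfst_", fst_tag(win, pr))
    iods <- call_islands(win, zc, ipar)
    islands[[tag]] <- iods
    write_bed(iods, file.path(cfg$out_dir, paste0("islands_", tag, ".bed")))
    write_tsv_file(attr(iods, "summary"),
                   file.path(cfg$out_dir, paste0("islands_", tag,
                                                 "_summary.tsv")))
    stat_cols <- intersect(
      c(paste0("pi_", pr), paste0("dxy_", fst_tag(win, pr)),
        paste0("pbs_", pr), "gc"), names(win))
    ctr <- compare_inside_outside(win, iods, stat_cols)
    contrasts[[tag]] <- ctr
    write_tsv_file(ctr, file.path(cfg$out_dir,
                                  paste0("inside_outside_", tag, ".tsv")))

    fst_c <- paste0("fst_", fst_tag(win, pr))
    theta <- vapply(pr, function(p) {
      n <- n_chromosomes(samples)[[p]]
      K <- sum(sites$called_count[, p] >= 2 &
                 sites$alt_count[, p] > 0 &
                 sites$alt_count[, p] < sites$called_count[, p])
      watterson_theta(K, n, sum(chrom_lengths))
    }, numeric(1))
    dt <- estimate_split_time(win, fst_c,
                              Ne = ne_from_theta(theta, cfg$mu),
                              islands = iods, n_boot = cfg$n_boot,
                              seed = cfg$seed)
    divtimes[[tag]] <- dt
    jsonlite::write_json(unclass(dt),
                         file.path(cfg$out_dir,
                                   paste0("divtime_", tag, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null")

    if (nrow(iods) > 0) {
      prof_cols <- intersect(c(paste0("pi_", pr[1]),
                               paste0("dxy_", fst_tag(win, pr)), zc),
                             names(win))
      prof <- island_profile(win, iods, prof_cols,
                             max_dist = cfg$profile_max_dist,
                             step = cfg$width)
      profiles[[tag]] <- prof
      write_tsv_file(prof, file.path(cfg$out_dir,
                                     paste0("profile_", tag, ".tsv")))
    }
  }

  perms <- list()
  if (!is.null(cfg$permutation_bed)) {
    ref <- read_bed(cfg$permutation_bed, chrom_lengths = chrom_lengths)
    for (tag in names(islands)) {
      if (nrow(islands[[tag]]) == 0) next
      pt <- perm_test(islands[[tag]], ref, chrom_lengths,
                      n_perm = cfg$n_perm, randomize = "both",
                      seed = cfg$seed)
      perms[[tag]] <- pt
      write_tsv_file(tibble::as_tibble(unclass(pt)[
        c("observed", "null_mean", "null_sd", "z_score", "p_empirical",
          "fold", "n_perm", "randomized", "mode")]),
        file.path(cfg$out_dir, paste0("permtest_", tag, ".tsv")))
    }
  }

  outputs <- list.files(cfg$out_dir, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(cfg$out_dir, "manifest.json"))
  manifest <- list(
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    n_sites = n_sites(sites),
    filter_report = attr(sites, "filter_report"),
    n_windows = nrow(win),
    islands = lapply(islands, function(x) attr(x, "summary")),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(sort(outputs))), basename(sort(outputs))))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(list(windows = win, islands = islands, contrasts = contrasts,
                 divtime = divtimes, profiles = profiles, perm = perms,
                 manifest = manifest))
}

# pair tag as used in dxy_/fst_ column names, honoring label order
fst_tag <- function(win, pr) {
  sub("^fst_", "", fst_col(win, pr[1], pr[2]))
}

write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
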