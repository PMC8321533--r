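#' Load a sample table (sample, population, ploidy)
#'
#' The sample table maps each sequenced individual to a population label
#' and a ploidy (1 for haploid males, 2 for diploid females).  The number
#' of sampled chromosomes per population -- the `n` used by all
#' estimators -- is the sum of ploidies.
#'
#' @param path TSV with header columns `sample`, `population`, `ploidy`.
#' @return A tibble of class `sample_table` with those three columns.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample\tpopulation\tploidy",
#'              "w1\tA\t2", "w2\tA\t2", "d1\tB\t1"), tf)
#' st <- load_sample_table(tf)
#' n_chromosomes(st) # A: 4, B: 1
#' @export
load_sample_table <- function(path) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("sample", "population", "ploidy")
  if (!all(need %in% names(x))) {
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  }
  sample_table(x$sample, x$population, x$ploidy)
}

#' @rdname load_sample_table
#' @param sample,population character vectors.
#' @param ploidy integer vector, each 1 or 2.
#' @export
sample_table <- function(sample, population, ploidy) {
  sample <- as.character(sample)
  population <- as.character(population)
  ploidy <- as.integer(ploidy)
  if (anyDuplicated(sample)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "))
  }
  if (any(is.na(ploidy)) || !all(ploidy %in% c(1L, 2L))) {
    stop("ploidy must be 1 or 2 for every sample")
  }
  if (any(is.na(population) | population == "")) stop("empty population label")
  out <- tibble::tibble(sample = sample, population = population,
                        ploidy = ploidy)
  class(out) <- c("sample_table", class(out))
  out
}

#' Sampled chromosomes per population
#' @param samples a `sample_table`.
#' @return named integer vector: sum of ploidies per population.
#' @export
n_chromosomes <- function(samples) {
  vapply(split(samples$ploidy, samples$population), sum, integer(1))
}

#' Population labels present in a sample table
#' @param samples a `sample_table`.
#' @return character vector of unique population labels, in order of
#'   first appearance.
#' @export
populations <- function(samples) unique(samples$population)
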