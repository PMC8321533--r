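Package: divscape
Title: Windowed Divergence Landscapes, Islands of Divergence, and
    Haplodiploid Divergence Times from Mixed-Ploidy Variant Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative population-genomic analysis of divergence
    landscapes from multi-sample VCFs with mixed ploidy (haploid males,
    diploid females). Computes nucleotide diversity, absolute divergence
    (dXY) and Hudson's FST in nonoverlapping windows, standardizes FST to
    Z scores, segments islands of divergence by threshold/merge/length
    rules, derives divergence-time-scaled branch lengths and the
    population branch statistic, tests region-set overlap by
    per-chromosome permutation, and estimates split times for
    haplodiploids from Watterson's theta with bootstrap confidence
    intervals. Includes a synthetic-data generator emulating divergence
    with and without window-specific barriers to gene flow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    IRanges,
    optparse
Config/testthat/edition: 3
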