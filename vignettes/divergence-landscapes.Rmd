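---
title: "Divergence landscapes, islands of divergence, and haplodiploid split times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence landscapes, islands of divergence, and haplodiploid split times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Closely related taxa that diverged recently — within-species population
pairs, cryptic species in sympatry, allopatric sister species — show
heterogeneous landscapes of genomic divergence.  Relative divergence
($F_{ST}$) forms localized peaks, *islands of divergence* (IoDs), whose
interpretation is contested: they can mark **barrier loci** that
resisted gene flow while the rest of the genome homogenized, or
**incidental islands** where linked selection in low-recombination
regions depressed diversity in both daughters (which inflates $F_{ST}$
without any barrier).  The two scenarios separate on *absolute*
divergence: $d_{XY}$ is elevated inside true barriers (longer
coalescence, no migrant lineages) but depressed inside incidental
islands (shorter coalescence inherited from the ancestor).

`divscape` implements the full windowed analysis for mixed-ploidy
variant data — social haplodiploid insects are the motivating system,
where males are haploid and females diploid — together with a
generative simulator so that every stage can be exercised and
calibrated without any external data.

## Estimators

All statistics are computed from per-site, per-population allele
counts $(a, n)$ ($a$ alternate alleles among $n$ successfully genotyped
chromosomes):

* $\pi$ (within-population diversity), per site
  $2a(n-a)/\{n(n-1)\}$ — the unbiased fraction of differing
  chromosome pairs;
* $d_{XY}$ (absolute divergence), per site
  $p_1(1-p_2) + p_2(1-p_1)$ — no sample-size correction is needed for
  cross-population pairs;
* Hudson's $F_{ST}$, per site a numerator
  $(p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1}$
  and denominator $p_1(1-p_2)+p_2(1-p_1)$, combined per window as a
  **ratio of averages** $\sum \mathrm{num} / \sum \mathrm{den}$.
  Hudson's estimator was chosen because it is the recommended
  two-population estimator, nearly unbiased under unequal and small
  sample sizes — essential here, where one population may contribute
  as few as 18 chromosomes.

Windows are 20-kb and nonoverlapping.  The per-base denominator for
$\pi$ and $d_{XY}$ defaults to the window length (minus masked bases):
input VCFs carry SNPs only, so unreported positions are treated as
monomorphic.  This is a uniform rescaling that cancels in every
inside/outside contrast; a per-SNP denominator (`denominator =
"n_sites"`) is available.  Windows with fewer than `min_snps = 10`
usable sites report `NA` and are excluded from all downstream
summaries; the threshold is configurable because no principled default
exists — it trades variance of window estimates against genome
coverage.

### Mixed ploidy

The sample table assigns each individual a ploidy of 1 or 2; $n$ per
population is the sum of ploidies.  Haploid genotypes may be encoded
as `0`/`1` or as homozygous diploid calls (`0/0`, `1/1`), both counting
one chromosome — variant callers emit both dialects.  A *heterozygous*
call in a haploid is impossible and indicates cross-mapping; the site
is dropped entirely (`drop_haploid_hets = TRUE`), mirroring standard
practice for haplodiploid data.  Missing genotypes decrement the
population's $n$ at that site; a site unusable in one pair remains
usable in others.

### ZFST and island calling

Window $F_{ST}$ is standardized per comparison as
$ZF_{ST} = (F_{ST} - \mathrm{median})/\mathrm{SD}$ over all non-NA
windows, so the non-NA $ZF_{ST}$ vector has median exactly 0.
Negative $F_{ST}$ values are retained; clamping would shift the
median.  Islands are called by threshold/merge/length rules:

1. flag windows with $ZF_{ST} \ge 2$ (the threshold is inclusive and
   configurable);
2. merge flagged windows whose edge-to-edge gap is at most 60 kb;
3. keep blocks strictly longer than 100 kb (block length includes
   bridged gaps);
4. optionally merge retained islands within 1 Mb of each other
   (`second_merge_gap`), bridging short $ZF_{ST}$ dips inside one
   large divergent region — intended for comparisons whose islands
   are large and few, not for fragmented landscapes.

The caller is deliberately rule-based rather than HMM-based so that
results are exactly reproducible from the stated parameters; the merge
is verified in the tests against a brute-force interval-union oracle
and against `IRanges::reduce`.

### Branch statistics

For a pair plus outgroup, each pairwise $F_{ST}$ is transformed to
drift-time units $T = -\ln(1 - F_{ST})$ (undefined at $F_{ST} = 1$,
returned as `NA` with a warning; small negative $F_{ST}$ gives small
negative $T$ and is retained so that branch sums stay exact).  The
population branch statistic for the focal population is
$\mathrm{PBS} = (T_{12} + T_{10} - T_{20})/2$; the two in-group
branches always sum to $T_{12}$, which the tests assert on every
window.

### Permutation tests of region overlap

Overlap between two region sets (e.g. IoDs × centromeric repeat
arrays) is tested by re-placing each region uniformly on its own
chromosome with its size preserved, recomputing the overlap statistic
(count of query regions touching the reference, or base pairs of
intersection), and taking
$p = (\#\{\mathrm{null} \ge \mathrm{obs}\} + 1)/(n_{\mathrm{perm}}+1)$.
Randomized regions may overlap one another by default (matching the
behavior of the standard `regioneR`-style null); a rejection-sampling
disjoint mode exists.  Z-scores and fold enrichment
($\mathrm{obs}/\mathrm{null\ mean}$) summarize effect size; depletion
is tested with `alternative = "less"`.  The calibration test in the
suite verifies that p-values are uniform under independently placed
region sets (500 replicate datasets).

### Split-time estimation for haplodiploids

Haplodiploids carry three autosome copies per breeding pair, so
$\theta_w = 3 N_e \mu$ and the drift clock runs as $T = t/(3 N_e)$.
The estimator:

1. $\theta_w = K/(a_n L)$ with $a_n = \sum_{i=1}^{n-1} 1/i$, $K$
   segregating sites, $L$ accessible bases (defaulting to total
   assembly length, which reproduces genome-wide summary tables);
2. $N_e = \theta_w/(3\mu)$ with $\mu = 3.6\times10^{-9}$ per site per
   generation by default;
3. windows overlapping IoDs are excluded — they reflect barrier
   history, not genome-wide drift — and
   $t = 3 N_e \cdot \overline{T}$ with $\overline{T}$ the mean window
   $T$; at one generation per year this is also the age in years;
4. a percentile bootstrap over windows (5,000 replicates) gives the
   95% CI.

When the two populations' $N_e$ estimates differ, the default uses
their arithmetic mean: the underlying model assumes a single shared
size, and the symmetric mean is the neutral choice; per-species or
fixed values can be supplied instead.  By Jensen's inequality the
window-mean $\overline{T}$ always exceeds $-\ln(1-\bar F)$ computed
from the mean $F_{ST}$; both are reported (`mean_T`, `headline_T`) and
the inequality is asserted on every run.

## The simulator

`sim_params()` + `simulate_dataset()` generate mixed-ploidy VCFs with
known truth.  Two populations split $t$ generations ago; each 20-kb
window belongs to a class:

| class | gene flow | diversity factor | emulates |
|---|---|---|---|
| `background` | $t_{\mathrm{eff}} = t(1-g)$ | $\lambda = 1$ | freely homogenizing genome |
| `barrier` | none ($t_{\mathrm{eff}} = t$) | $\lambda < 1$ | barrier loci in low-recombination regions |
| `lowrec_background` | as background | $\lambda < 1$ | incidental islands (linked selection only) |

Gene flow is modelled as an effective-time reduction rather than
explicit migration — sufficient to generate the $F_{ST}$ and $d_{XY}$
contrasts the pipeline must detect.  Per window the drift-level
fixation index is $F = 1 - e^{-t_{\mathrm{eff}}/(3 N_e \lambda)}$
($\lambda$ scales the local effective size, as linked selection does).
Ancestral polymorphic sites are placed at density
$\theta_{\mathrm{anc}}\lambda$ per base with frequencies from a
discretized neutral SFS ($\propto 1/k$ on a 1/200 grid); daughter
frequencies are Balding–Nichols beta draws with that $F$.  Post-split
mutations are injected as fixed differences at rate
$2\mu t_{\mathrm{eff}}$ per base — this biases $\pi$ slightly low but
makes $E[d_{XY}]$ analytic.  Diploids are Hardy–Weinberg
$\mathrm{Bin}(2,p)$ draws, haploids Bernoulli.  Balding–Nichols
sampling rather than a coalescent or forward simulator keeps the
generator fast, dependency-free and *exactly* parameterized by the
same $F = 1-e^{-T}$ mapping the estimators invert.

### Desk-scale defaults, and what they do and do not show

The defaults compress the empirical system (hundreds of thousands of
individuals, hundreds of genomes, a 252-Mb assembly) to desk scale,
preserving the contrasts rather than the absolute sizes:

* $N_e = 1000$, three 4-Mb chromosomes of 200 windows each, one
  special block of 20 windows per chromosome (10% of the genome, the
  order observed for sympatric islands);
* sympatric mode: $t = 1595$, $g = 0.5566$, $\lambda = 0.2$, chosen so
  the *drift-level* background and barrier $F$ are $\approx 0.21$ and
  $\approx 0.93$ — the two modes of the bimodal sympatric landscape;
* allopatric mode: $t = 383$ (background $F \approx 0.12$), no gene
  flow, $\lambda = 0.2$ in low-recombination windows
  ($F \approx 0.47$ there);
* $\mu = 3.4\times10^{-7}$: scaled up by the same factor that $N_e$
  is scaled down, so the per-base mutation input $2\mu t$ — and with
  it the direction and ~20% magnitude of the sympatric $d_{XY}$
  elevation — matches the empirical regime.  In neutral mode
  $\mu = 0$: the split-time model maps $F_{ST}$ to drift alone, and
  its recovery experiment is run under that model's assumptions;
* $\theta_{\mathrm{anc}} = 0.003$/base (~60 SNPs per window) as the
  general-purpose default; the split-time recovery experiment uses
  the study-scale SNP density of 0.018/base (~360 SNPs per window),
  the regime in which the window-level Hudson ratio and the convex
  $T$ transform are effectively unbiased.  At much sparser densities
  the two small-sample biases (ratio-of-sums, Jensen) no longer
  cancel and coverage of the bootstrap CI degrades — a property of
  the estimator worth knowing before applying it to sparse data.

Realized window $F_{ST}$ *includes* the injected fixed differences and
therefore sits above the drift-level targets (sympatric background
$\approx 0.6$ realized) — exactly as real between-species $F_{ST}$
includes post-split substitutions.  The moment-recovery test of the
generator therefore runs with $\mu = 0$ to isolate the drift component
that $F$ parameterizes.

What passing tests show: the estimators are exact against enumeration
oracles; the island caller is exact against interval-union oracles;
the permutation p-values are calibrated; the split-time estimator
covers a known truth; and the generative barrier/no-barrier regimes
reproduce the qualitative $d_{XY}$ contrast (elevated inside sympatric
islands, depressed inside allopatric ones).  What they do not show:
robustness to real-data pathologies the generator omits — linkage
within windows (sites are independent given $F$), mapping artifacts,
recombination-rate variation along real maps, segregating (rather than
fixed) post-split mutations, and selection acting site by site.

## Numerical choices and degenerate inputs

* Coordinates: VCF positions are 1-based; all interval arithmetic is
  0-based half-open; the conversion happens in one place.
* `zfst()` errors on fewer than 2 usable windows or zero SD (a
  degenerate landscape) rather than returning NaNs.
* $F_{ST}$ sites with zero denominator (both populations monomorphic
  for the same allele) are excluded from the window ratio.
* Window $F_{ST} = 1$ windows are excluded from split-time estimation
  (infinite $T$) with logged counts, as are NA windows.
* `perm_test` reports $p \ge 1/(n_{\mathrm{perm}}+1)$ always; the
  Z-score is NA when the null is constant.
* Bootstrap resampling is chunked to bound memory at ~160 MB
  regardless of window count.
* The island merge never crosses chromosome boundaries, and raising
  the flagging threshold can only shrink total island bp (asserted as
  a property test).

## Problem sizes used in the test suite

Unit tests run on fixtures of tens of windows.  The calibration
experiments use: 500 replicate datasets × 200 permutations
(permutation uniformity); 100 replicates of 2,000 windows with 5,000
bootstrap replicates each (split-time coverage); 600-window genomes
for the sympatric/allopatric contrast; and ~400k sites for the
generator moment checks.  These sizes give Monte-Carlo error
comfortably inside the asserted tolerances while keeping the full
suite in the tens of minutes on a single core.
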