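---
title: "Methods: sweep scanning and marker validation in beakscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sweep scanning and marker validation in beakscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beakscan)
```

`beakscan` detects selective sweeps between two phenotype-labelled duck
populations from biallelic SNP genotypes and carries the resulting
candidate loci through linkage, association and expression validation.
This vignette documents the statistical model behind each stage, the
tunable parameters and their defaults, the simulator used to exercise the
pipeline, and the numerical choices made where the design was genuinely
open.

## The genotype substrate

Everything operates on a `geno_matrix`: samples × biallelic SNPs with
alternate-allele dosage codes (0/1/2, `NA` missing), 1-based positions,
and exactly one group label per sample. Indels and multi-allelic records
are excluded at VCF parsing. Internal coordinates are 1-based inclusive
everywhere (the VCF convention); BED input is converted at the boundary
and converted back on output.

Variant filtering retains sites with QUAL > 30, mean per-sample depth
strictly between 5× and 18×, and missing ("deletion") rate below 0.1 —
all strict inequalities, so a site at exactly QUAL 30 or 18× is removed.
Depth is interpreted as *mean per-sample* depth: the per-sample
`FORMAT/DP` average over called samples where available, otherwise the
site `INFO/DP` total divided by the number of called samples. The
missing rate is computed per site across all labelled samples, not per
population: missingness is a property of the site assay, and a per-group
rate at these sample sizes (20–40 birds) would be too noisy to filter
on. A site lacking a quality or depth annotation passes that criterion
rather than failing it, so minimal VCFs still flow through the pipeline.

## Sliding-window scan

Windows of `size` = 10,000 bp advance by `step` = 5,000 bp from position
1 of each chromosome, so each SNP belongs to (at most) two windows. At
10 kb, a window in a typical resequencing panel holds few enough linked
variants for the window statistics to be informative, while 5-kb steps
give half-overlap resolution. Trailing windows extending past the last
observed position are emitted but flagged `partial` and excluded from
threshold estimation, so ragged chromosome ends cannot distort the
empirical tails.

**Nucleotide diversity.** Per site, θπ uses the unbiased mean pairwise
difference `2·n_alt·n_ref / (n·(n−1))` over the `n` called alleles of a
group; sites with fewer than two called alleles in a group are skipped
for that group. Window diversity sums site values and divides by the
window *span* (10,000 bp), not by the SNP count: diversity per base pair
is the quantity that is comparable across windows with different SNP
densities.

**Differentiation.** The default estimator is Weir & Cockerham (1984):
per site the among-population (a), among-individual (b) and
within-individual (c) variance components, aggregated per window as the
ratio of sums `Σa / Σ(a+b+c)` — the "weighted" form, which is the
community default for windowed scans because it weights sites by their
information content rather than averaging unstable per-site ratios. A
window of sites fixed for opposite alleles yields exactly 1; sites
monomorphic for the same allele in both groups contribute nothing. A
Hudson-type estimator (Bhatia et al. 2013 formulation) is available via
`estimator = "hudson"` for sensitivity checks; it is never mixed with
the default within a scan.

**The π-ratio.** `log2(θπ,pop1 / θπ,pop2)` with the numerator group
named explicitly by the caller (`numerator =`; the scan refuses to guess
an orientation). The ratio is undefined when either group's window
diversity is zero. We deliberately do *not* patch zero-diversity windows
with a pseudocount: a pseudocount would manufacture the most extreme
ratios exactly where the data say least, and those windows are instead
excluded from the ratio's quantile computation and can never be
selected.

**Selection rule.** With tail fraction `q` = 0.05, the cuts are the
empirical `1−q` quantile of window F_ST and the `q` and `1−q` quantiles
of the log2 ratio (type-7 linear-interpolation quantiles, R's default).
The two ratio tails are computed per side, so they are asymmetric
whenever the ratio distribution is; both tail statistics are taken on
the identical window grid. A window is selected when it lies at or above
the F_ST cut **and** at or beyond either ratio cut — ties at a cut are
included (`>=`/`<=`), since excluding them would make selection depend
on floating-point noise at the threshold. Selected windows that overlap
or are book-ended merge into maximal regions; genes annotate a region on
any 1-bp overlap, and gene lists are deduplicated.

**PCA.** Sites are centred by mean dosage and scaled by `√(2p(1−p))`
(the dosage standard deviation under HWE), missing calls mean-imputed
per site, monomorphic sites dropped, and sample scores taken from the
singular value decomposition. Axis signs are arbitrary.

## Extreme-difference loci and association

A locus is an *extreme-difference* locus at threshold `min_freq` when
its alternate-allele frequency is ≥ `min_freq` in one group and
≤ `1 − min_freq` in the other, in either orientation — operationalising
"the ref sequence is essentially private to one phenotype and the alt to
the other". The default 0.95 is the loosest round threshold that still
admits loci where a single bird out of 40 carries the minor genotype
(frequency 0.975/0.025, which the packaged 41-locus table contains)
while rejecting any 0.9/0.1 pattern. The filter is monotone: raising
`min_freq` never adds loci.

Association uses the Pearson chi-square without continuity correction,
by default on the 2×2 allele-count table (ref alleles
`2·n_refref + n_het`; alt alleles `n_het + 2·n_altalt`), which is the
form that reproduces the published marker statistic (40.833 on the F2
table); the genotype-level 2×3 test is available via
`assoc_test(level = "genotype")`, with all-zero genotype classes dropped
so the degrees of freedom adjust. The packaged breed tables also carry
printed chi-square values (68.2, 51.3, 49.9, 31.7) that are not
recoverable from their printed counts under Pearson,
likelihood-ratio or Yates variants at either allele or genotype level;
the package therefore reports its own computed statistics alongside
those tables rather than forcing agreement. Reported frequencies are
rounded half-up at 2 decimals only in the presentation layer
(`frequency_report()`); all internal arithmetic is exact.

## Linkage disequilibrium

Two-locus haplotype frequencies are estimated from unphased genotypes by
EM. Only double heterozygotes are phase-ambiguous; the E-step splits
their gametes between coupling and repulsion in proportion to the
current haplotype-frequency products, and the M-step re-counts gametes,
which preserves the observed allele-frequency margins from the first
iteration onward. Convergence is declared when the largest frequency
change drops below 1e-10 (cap 1,000 iterations), and the multinomial
log-likelihood is asserted non-decreasing at every step.

With margins fixed, the likelihood in the single free parameter can be
bimodal (a coupling and a repulsion mode). EM therefore runs from three
starts — uniform, coupling-leaning and repulsion-leaning — and keeps the
best fit. When the two orientations fit *exactly* equally (e.g. a table
of pure double heterozygotes), the data carry no phase information; the
symmetric stationary point (0.25, 0.25, 0.25, 0.25) is returned and
flagged `saddle = TRUE` rather than an arbitrary orientation.

From the fitted frequencies: `D = f_altalt − p1·p2`; `D′ = |D|/Dmax`
with the usual sign-dependent bound; `r² = D²/(p1 q1 p2 q2)`. A
monomorphic margin gives `NA` statistics, not an error. Individuals
missing at either locus are excluded from that pair only (pairwise
deletion), keeping per-pair sample sizes honest. "Highly linked" is
summarised as the fraction of defined pairs with r² ≥ 0.8, the
conventional strong-LD cut-off in Haploview-style analyses; the
threshold is a parameter.

## Expression

The 2^−ΔΔCt method: technical replicates are averaged on the Ct scale,
ΔCt = Ct_target − Ct_reference per sample, ΔΔCt is referenced to the
mean ΔCt of an explicit calibrator group, and fold = 2^−ΔΔCt. Group
testing is one-way ANOVA on ΔCt — the approximately normal, log-linear
scale — not on folds, which are log-normal; with two groups the F
statistic equals the squared pooled-variance t statistic. Zero
within-group variance everywhere yields a flagged `NA` p-value.
Amplification-efficiency correction (Pfaffl) is out of scope.

## The simulator, and what passing tests mean

`simulate_two_pop()` draws SNP positions uniformly on one chromosome;
outside the planted interval both populations share an ancestral
alternate-allele frequency drawn per SNP from Beta(0.8, 0.8) — a
U-shaped spectrum resembling the folded site-frequency spectrum of a
resequencing panel, with most sites near fixation in one direction and
a polymorphic middle; inside the interval each population gets its own
fixed frequency. Genotypes are binomial draws from the population
frequency, i.e. exact HWE within groups and free recombination between
sites. The standard study conditions are 2 × 20 diploids, 2,000 SNPs on
1 Mb, a planted interval at 400,001–500,000 bp with alternate
frequencies 0.98 vs 0.02.

The simulator is a genotype-level emulator, not a coalescent: every
statistic in the pipeline depends only on genotype counts, so this is
sufficient to verify the estimators and the selection logic, and it is
fast. It does not model background LD (the LD module gets its structure
from `simulate_haplotype_pairs()`, which draws true phased haplotypes
and collapses them), demography, recombination maps, or
sequencing-error processes. Passing tests therefore demonstrate correct
statistics and selection behaviour under idealised two-population
structure — not calibrated performance on real resequencing data, where
linked neutral variation, uneven coverage and call errors widen the
tails of both scan statistics.

Test and check problem sizes were chosen to exercise each property at
the smallest scale where the signal is unambiguous: 2,000-SNP panels for
scan recovery and PCA separation (5 seeds for sweep recovery),
50–5,000 individuals for EM consistency, 100–1,000 random
configurations for the brute-force oracle comparisons.

## Known limitations

* The scan assumes exactly two groups; multi-population contrasts are
  out of scope.
* Window F_ST can be slightly negative on undifferentiated data (an
  unbiasedness property of the Weir–Cockerham estimator); values are not
  truncated.
* Chromosome lengths default to the largest observed position, so a
  SNP-free chromosome tail is invisible to the scan unless
  `chrom_lengths` is supplied.
* Haplotype-block partitioning (Gabriel confidence intervals) and
  multi-locus phasing are not implemented; LD is strictly pairwise.
* Genome-wide significance modelling is not attempted: tail thresholds
  are empirical quantiles of the scanned data themselves.
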