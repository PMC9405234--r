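---
title: "Methods: LD, haplotype blocks, Ne and selection scans for closed herds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LD, haplotype blocks, Ne and selection scans for closed herds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ldsweep` implements the population-genomics workflow used to characterize
small, closed livestock populations from SNP-array genotypes: quality
control, pairwise linkage disequilibrium (LD) and its decay with distance,
Gabriel-definition haplotype blocks with a cross-herd comparison, LD-based
historical effective population size (Ne), and the haplotype-based
selection statistics iHS and XP-EHH with candidate-region annotation. This
vignette records the models, the tunable parameters that matter, the
numerical choices, and what the bundled simulator can and cannot tell you
about real data.

## Data model

Genotypes are held as a samples x variants matrix of alt-allele dosages
(0/1/2, `NA` for a missing call); phased data as a (2 x samples) x variants
binary matrix whose rows `2k-1, 2k` belong to sample `k`. Coordinates are
1-based inclusive internally (the PLINK/VCF convention); exported BED is
0-based half-open, with the conversion confined to the I/O layer. Missing
dosages are never silently imputed: each stage states its policy (PCA mean
imputation, pairwise-complete LD, exclusion elsewhere). Multiallelic VCF
records are skipped with a logged count because every statistic here is
defined on biallelic chip SNPs.

Ancestral alleles, required by iHS, come with this priority: simulator
truth, then the VCF `AA` INFO tag, then a user table; if none is available
the reference allele is assumed ancestral with a loud warning. Array data
rarely comes with a reliable polarization, and a mispolarized SNP flips the
sign of its uniHS, so treat unpolarized iHS signs with caution; |iHS| and
XP-EHH are unaffected.

## Quality control

SNPs are filtered in a fixed, logged order: non-autosomal and
unknown-position variants, call rate < 90%, minor allele frequency (MAF)
< 0.02, exact Hardy-Weinberg p < 1e-6; then samples are pruned at pi-hat
> 0.45. The order is a package decision (counts depend on it); each SNP is
attributed to the first filter it fails and a total-unique count is
reported. The Hardy-Weinberg test is the exact conditional test (sum of
probabilities of heterozygote counts, given allele counts, no more probable
than observed), not the chi-square approximation; it matches a brute-force
enumerator to 1e-12 for every table with up to 20 individuals. The MAF rule
is "remove MAF < 0.02", i.e. a SNP at exactly 0.02 survives.

Relatedness uses the method-of-moments IBD decomposition of
identity-by-state sharing given sample allele frequencies; pi-hat =
P(IBD=1)/2 + P(IBD=2), clamped to [0,1]. Pruning is greedy and
deterministic: while any pair exceeds the threshold, the member of the
worst pair with the higher mean pi-hat (ties: lexicographic id) is removed.
Pi-hat needs informative frequencies; below ~50 usable SNPs the estimates
are unstable and a warning fires. PCA standardizes dosages by
`sqrt(2p(1-p))` after per-variant mean imputation and reports eigenvalues
over the covariance trace.

## LD and its decay

Two r-squared estimators are available for unphased data. The default
"composite" estimator is the squared Pearson correlation of dosage vectors
over pairwise-complete samples, the conventional chip-data choice; the "em"
estimator resolves double-heterozygote phase with a two-locus EM and
applies the haplotype-frequency formula
`r2 = (P_AB P_ab - P_Ab P_aB)^2 / (P_A P_a P_B P_b)`. On collapsed phased
data the EM estimate converges to the phased truth (tested at n = 1000
within 0.02).

Pair formation mirrors a windowed PLINK run: intra-chromosomal pairs within
99,999 SNPs and 1000 kb by default. A reporting threshold (default r2 >=
0.2, the replication convention) omits weak pairs from the *report*; this
conditions the reported mean r2 upward, substantially so in genome-wide
summaries, which is why the pipeline reports the thresholded mean only in
replication mode and always computes decay and Ne from unthresholded
streams. Decay is summarized in half-open distance bins (last bin closed)
at the three conventional granularities (10 kb / 1 kb, 100 kb / 10 kb,
1000 kb / 100 kb).

## Haplotype blocks

Blocks follow the Gabriel confidence-interval definition with the
Haploview-default constants. |D'| is profiled on a 0.01 grid with allele
frequencies fixed at sample estimates and D sign-normalized; the 95% CI is
the 5th-95th percentile of the normalized likelihood mass (a deterministic
construction, unlike a bootstrap). A pair is "strong LD" when the CI lower
bound is >= 0.70 and the upper >= 0.98, and "strong recombination" when the
upper bound is < 0.90. A span is a candidate when its end-point pair is in
strong LD, it spans <= 1000 kb and >= 3 usable markers (MAF >= 0.05 inside
the search), and >= 95% of its informative pairs are strong LD (80% for
3-marker spans). Overlaps are resolved greedily by descending bp span,
ties to the leftmost start; 2-SNP blocks are never reported, removing the
spurious micro-blocks that inflate block counts.

Within-block haplotype frequencies are counted exactly from phased input;
for unphased input a full-enumeration multi-locus EM (50 iterations or
log-likelihood change < 1e-6) is run only for blocks of <= 10 SNPs, because
the enumeration grows exponentially; wider unphased blocks report no
frequencies. The block-set summary includes a "mean haplotype frequency"
(mean over blocks of the mean frequency of that block's observed
haplotypes) for comparability with published tables; no single standard
definition of that statistic exists, so treat it as descriptive only.
Genome coverage is relative to the analysed span (first to last retained
SNP per chromosome), not the assembly length. Two blocks are "shared"
between herds when they overlap by >= 1 bp on the same chromosome
(a minimum-overlap fraction is configurable).

## Effective population size

Ne(t) inverts the drift expectation `E[r2_adj | c] = 1/(alpha + 4 Ne c)`
with `r2_adj = r2 - 1/(beta n)` (beta = 1 for unphased chip genotypes,
2 when the gametic phase is known) and `t = 1/(2c)` generations ago.
Distances map to recombination fractions linearly at 1 cM/Mb by default
(Sved's mapping is available; the two agree within 2% for c <= 0.02).
Pairs are binned in 30 log-spaced bins from 50 to 4000 kb; each bin's
representative distance is the harmonic mean of its pair distances
(midpoint optional). alpha defaults to 1 (no mutation correction), with 2
and 2.2 exposed. Negative adjusted values are kept and averaged; bins whose
mean inverts to a non-positive Ne are flagged invalid rather than dropped
silently.

Three practical cautions. The input stream must be unthresholded - the
function refuses a stream with omitted low-r2 pairs, since conditioning on
large r2 biases E[r2] downward-in-Ne. SNPs should be MAF-filtered (>= 0.05)
first: rare variants cannot carry high r2 and drag bin means down, which
inflates Ne - the workflow stages do this filtering. And on a single
chromosome the precision is limited by the number of independent LD blocks,
not by the SNP count: per-bin estimates scatter far more than binomial
intuition suggests, so the trajectory's median over a time window is the
robust summary (the acceptance checks use the median over t in [10, 100]).

## Selection scans

EHH for a core allele is the probability that two random carrier
haplotypes are identical from the core out to a position; it is 1 at the
core and non-increasing outward. Integration (trapezoid over bp) stops
after the first point below 0.05 and hard-stops at inter-SNP gaps over
500 kb. iHS is `ln(iHH_A / iHH_D)` standardized to mean 0, sd 1 within
derived-allele-frequency bins (50 bins of width 0.02); adjacent bins are
merged until each standardization group holds at least 20 SNPs, because a
sparse bin standardizes a sweep's hitchhikers against themselves and erases
the signal. The significance transform is
`piHS = -log10(2 Phi(-|iHS|))`, so piHS = 3 corresponds to |iHS| = 3.29
(two-sided p = 0.001).

Candidate regions are 1-Mb windows stepped by 990 kb (adjacent windows
overlap by 10 kb; the alternative 10-kb-step reading of that convention is
configurable), dropped below 10 scored SNPs, ranked by the density of
"extreme" SNPs, with the top 1% (at least one) flagged. Three extreme-SNP
rules are provided because published chip scans mix them: a piHS >= 3
threshold, a plain |iHS| threshold, and the genome-wide top 1% of |iHS|
(the SNP-level candidate convention). The fixed thresholds are
appropriate for dense, genome-wide data; at a few thousand SNPs the
top-percentile rule is the one that yields a well-defined ranking, and it
is what the workflow uses.

XP-EHH compares pooled site EHHS between two populations at identical
variant sets: all haplotypes, partitioned by the core allele, normalized to
1 at the core (the Tang normalization used by the standard implementations;
it removes core-frequency variance from the scores). The raw
`ln(iES_1/iES_2)` is standardized genome-wide; candidates are runs of >= 3
consecutive SNPs above 4.0, positive runs meaning extended haplotypes (and
hence selection toward fixation) in population 1. The statistic is exactly
antisymmetric under population swap. SNPs monomorphic in one population are
excluded from iHS (it needs both allele classes) but retained for XP-EHH.

Candidate regions from either scan are extended by 200 kb both ways,
merged, clamped to chromosome bounds, and intersected with gene/QTL
intervals under closed, >= 1 bp overlap semantics (BEDTools-compatible;
verified against a quadratic oracle). Gene identifiers are case-folded and
version-stripped before Venn-style set comparison. Enrichment analysis
against external databases is out of scope; the gene lists are formatted
for upload to such services.

## The simulator and what passing tests mean

The Wright-Fisher generator is forward-in-time for direct control of the
size history and sweeps: founders draw site frequencies from the neutral
SFS (P(i copies) proportional to 1/i) or, in "array" mode, uniformly on
0.05-0.95 to emulate the common-variant ascertainment of genotyping chips
(the array data this workflow targets shows exactly that flattened
spectrum). Each generation: fitness-weighted parent sampling, meioses with
Poisson crossovers on the genetic map (Haldane, no interference), optional
viability selection 1 : 1+s : 1+2s at one sweep site. Selection switches
off when the allele reaches a target frequency, so a scenario can present
a sweep "in flight" (where iHS has power) or near fixation (XP-EHH's
regime). A single seed drives every draw; per-module reseeding is
forbidden, and a fixed seed reproduces output bit for bit.

Default study conditions emulate two sister herds: 200 founders declining
to 100 per herd, split at generation 80 of 150, 2500 SNPs on one 50-Mb
chromosome, 50 diploids sampled per herd. The sweep-power conditions use
N = 500, a 100-Mb chromosome, 5000 SNPs, split at generation 60, s = 0.1
from 0.5-3% standing frequency, 75 samples; detection is "a candidate
within 2 Mb of the sweep locus", 2 Mb being the expected hitchhiking
footprint at 2Ns ~ 100 (the iHS signal of a partial sweep peaks in the
flanks, not at the swept core, so locus-exact coverage is not the right
check). The parameter-recovery conditions are a constant N = 100, 200
generations, 5000 array-ascertained SNPs on 100 Mb, 50 samples.

What the simulator does not emulate: genotyping error, a realistic cattle
recombination map, gene conversion, mutation after initialization,
overlapping generations, or admixture. Passing recovery tests therefore
demonstrates that the estimators are correct for the model they assume,
not that real-herd estimates are unbiased; in particular real chip
ascertainment is more complex than the uniform-MAF emulation, and
LD-based Ne on real data inherits every caveat of the drift expectation.
One desk-scale limitation deserves emphasis: with a single ~100-Mb
chromosome, the top-1%-density rule yields a single candidate window and
genome-wide score standardization rests on only ~50 independent background
blocks, so sweep-detection power sits near - and sometimes below - the 80%
working target that a 2.5-Gb genome would clear comfortably.

## Determinism and degenerate inputs

Every stochastic step flows from an explicit seed; reruns are
byte-identical. Degenerate inputs are flagged rather than absorbed:
all-missing variants get `NA` frequencies, monomorphic loci make r2 and D'
undefined (`NA`, never 0), Hardy-Weinberg returns 1 for monomorphic tables,
empty decay bins report `n_pairs = 0` with `NA` statistics, SNPs with
fewer than two carriers of an allele are skipped by EHH with a log, and a
QC run that empties the panel warns but still returns its report.
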