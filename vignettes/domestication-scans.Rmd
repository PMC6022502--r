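---
title: "Detecting canine domestication sweeps with simulation-calibrated scans"
author: "DomestiScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting canine domestication sweeps with simulation-calibrated scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Village dogs and gray wolves differ at loci that responded to selection
during domestication. A candidate domestication region (CDR) is a genomic
interval where village dogs show strong allele-frequency differentiation
from wolves, depleted diversity consistent with a selective sweep, and a
swept haplotype that was already present in Neolithic dogs — the last
condition separating ancient domestication sweeps from recent breed-era
selection. DomestiScan implements this filter cascade as a reusable
pipeline over three window statistics, a copy-number differentiation scan,
and a permutation-calibrated gene-ontology enrichment, together with a
synthetic-cohort generator that makes every stage testable without any
sequencing data.

## Statistics and their models

**Hudson F~ST~.** Per biallelic site, with alternate-allele frequencies
$p_1$ (dogs) and $p_2$ (wolves) and $n_1$, $n_2$ individuals,

$$F_{ST} = \frac{(p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} -
\frac{p_2(1-p_2)}{n_2-1}}{p_1(1-p_2) + p_2(1-p_1)}.$$

The numerator carries the squared frequency difference minus
finite-sample corrections; sites where both populations are fixed for the
same allele have an undefined estimator and are excluded rather than set
to zero. Windows (200 kb, 50-kb step, at least 10 SNPs) score the ratio
of the summed numerators to the summed denominators ("ratio of
averages"), which is more stable than averaging per-site ratios. Sample
sizes enter as numbers of *individuals*; this follows the printed formula
of the source methodology and leaves a small $O(1/n)$ negative offset in
the per-site estimator at panmixia (about $-0.012$ for $n = 43$), which
is irrelevant for threshold-calibrated scans because the null is
simulated under the same convention. In the X-nonPAR, where males are
haploid, $n$ is the effective chromosome count divided by two.

**Pooled heterozygosity.** Per window,
$H_P = 2\,\Sigma n_{MAJ}\,\Sigma n_{MIN} / (\Sigma n_{MAJ} + \Sigma
n_{MIN})^2$, where the sums run over the per-site dog major- and
minor-allele counts. $H_P$ approaches 0 in swept windows and 0.5 when
major and minor counts balance. The major/minor axis is assigned within
modern dogs, with ties resolved toward the reference allele, and is
frozen before ancient samples are pooled.

**ΔH~P~ and the ancient-haplotype veto.** ΔH~P~ is the change in window
H~P~ when the two ancient dog genomes are added to the pool. Ancients
homozygous for the modern major haplotype can only decrease H~P~;
ancients carrying a different haplotype increase it. The veto removes
the 5% of windows with the largest ΔH~P~ (the genome-wide 95th
percentile of the ΔH~P~ = H~P~(with) − H~P~(without) distribution). We
note a subtlety: the source text reads "greater than the 5th percentile
… removed", which taken literally would discard 95% of all windows and
would also discard every fully swept window whose carrier ancients leave
ΔH~P~ at exactly 0; the published filtration accounting (hundreds of
windows surviving this step) and the stated intent — excluding regions
where the selected haplotype is *not* found in ancient dogs — both
require the upper-tail reading implemented here.

**XP-CLR.** The cross-population composite likelihood ratio treats the
wolf (reference) frequency $p_2$ at each SNP as known and models the dog
frequency as a truncated Gaussian drift around it with variance
$\omega\,p_2(1-p_2)$, with the mass pushed past 0 or 1 absorbed as
fixation. Under a sweep centred at a grid point, a lineage at genetic
distance $r$ Morgans escapes hitchhiking with probability
$c = 1 - \exp(-r/s)$, where $s$ is a selection scale maximised over a
grid; with probability $p_2$ the swept haplotype carries the alternate
allele, mapping a pre-sweep frequency $x$ to $(1-c) + cx$, and otherwise
to $cx$. The observed dog allele count is binomial given the frequency,
integrated by Gauss–Legendre quadrature (16 nodes). The score at a grid
point is twice the composite log-likelihood gain of the best $s$ over
the neutral model ($s = 0$, defined as $c = 1$), hence non-negative by
construction. Scores are computed every 2 kb using the SNPs within 25 kb
of the point, averaged in 25-kb windows (10-kb step, at least five scored
grid points), and merged within 50 kb after thresholding.

The original method's internals (drift variance, selection grid, SNP
weighting) are not printed in the source methodology, so they are
implementation-defined here: $\omega$ is estimated genome-wide as the
mean of $(p_1-p_2)^2 / (p_2(1-p_2))$ with the reference frequency clamped
to $[1/(2n_2+1), 1 - 1/(2n_2+1)]$ (this includes binomial sampling noise
and is therefore slightly conservative), and the default selection grid
is $s \in \{0, 10^{-4}, 3\times10^{-4}, 10^{-3}, 3\times10^{-3},
10^{-2}\}$ Morgans, spanning sweep footprints from tens of kilobases to
about a megabase at 1 cM/Mb. The implementation is validated by
invariants (null reduction, score monotonicity in differentiation,
planted-sweep recovery), not by numeric identity with the original
executable, and its absolute score scale differs from the original's:
our simulation-calibrated 99th percentile is ~15 where the source
pipeline reported 19.78.

**V~ST~.** For windowed copy-number estimates,
$V_{ST} = (V_T - V_S)/V_T$, where $V_T$ is the variance of all samples'
copy numbers and $V_S$ the size-weighted mean of the within-population
variances. Population variances use denominator $N$, so identical dog
and wolf distributions give exactly 0 and fixed differences give exactly
1 (the cited statistic's source does not specify the denominator).
Copy numbers come from windowed read depth (3-kb windows): depths are
GC-corrected per sample by 1% GC bins of designated control windows
(windows in bins with fewer than a configurable number of control
windows — 100 by default, smaller in the desk-scale tests — are flagged
uncorrectable), then scaled so control windows average copy number two.
Male X-nonPAR estimates are doubled before V~ST~. Outliers require a
copy-number range of at least 1.5 across samples, a Z-score above 5
(autosomes, X-PAR) or 3 (X-nonPAR), and support from more than one
window. The "evidence of copy number variation" gate is implemented as
the range pre-filter applied before the Z-transform, the ordering being
unstated in the source.

**Enrichment.** Genes within 50 kb of candidate regions form the test
set. Each GO term is scored by the parent–child hypergeometric test
(union variant: the sampling universe is the union of the parents' gene
sets; the union variant is the common default where the cited method
offers union and intersection). Because gene length, clustering and
annotation density bias any genomic interval test, significance is
calibrated by shuffling the regions uniformly along their own
chromosomes (lengths preserved, overlaps and optional gap masks
avoided): $p_{perm} = (X_{perm}+1)/(N+1)$ with $X_{perm}$ the number of
shuffles whose parent–child p-value is at or below the observed one
(ties count, conservatively). Enriched terms must additionally be
supported by more than one locus and more than one gene. No global
multiple-testing correction is applied, mirroring the source analysis;
reports should carry the full-test-count caveat.

## The neutral null

Thresholds for F~ST~ (99th percentile), H~P~ (0.1th percentile) and
XP-CLR (99th percentile) are taken from window statistics pooled over
neutral replicates simulated under a demographic model, scanned with
exactly the real-data parameters. Pooling across replicates (rather than
averaging per-replicate percentiles) is the implemented and tested
choice. Simulated SNP sets can be matched to a real dataset by applying
the same minor-allele-count rule and uniformly thinning to the real
per-chromosome SNP counts. The X chromosome is excluded from
simulation-calibrated thresholds — the demographic model describes
autosomes — and uses the empirical Z mode instead (Z ≥ 5 autosome/X-PAR,
Z ≥ 3 X-nonPAR, transformed separately per partition because drift
expectations differ).

The demography is configurable (YAML: named lineages with diploid sizes;
ordered size changes, splits and migration pulses; see
`readDemographyConfig()` and the synthetic example under
`inst/extdata/`), so multi-lineage histories can be expressed. The
default, `twoPopModel()`, is a deliberately simple two-population
history fixed once from published canine demography: dog and wolf
lineages of diploid size 13,000 and 17,000 splitting 5,000 generations
ago (15 kya at 3 years/generation) from a 32,000-strong ancestral
population, with a post-split dog bottleneck of 2,500 ending (looking
into the past) 4,500 generations ago; mutation rate 4×10⁻⁹ per site per
generation; uniform recombination at 1 cM/Mb. These values are choices,
not fits: they produce dog–wolf differentiation and dog diversity in the
range reported for village-dog cohorts, and the resulting calibrated
F~ST~ and H~P~ thresholds land within ~10% of the published full-scale
values, while the XP-CLR threshold is ~20% low (see above).

## The synthetic cohort generator

Genotypes are simulated backward in time with a structured coalescent
over independent, non-recombining blocks (20 kb by default): each block
draws its own genealogy under the demography, mutations fall on branches
at rate μ per site per generation (infinite sites), and diploid samples
pair consecutive chromosomes. Free recombination between blocks and none
within is a deliberate simplification of a full
coalescent-with-recombination: window statistics at the 25–200-kb scale
only need linkage at sub-window scale, and the block length is a
parameter if stronger or weaker linkage is wanted. Consequences: linkage
decays as a step function at block boundaries rather than smoothly, and
long-range LD is absent, which makes window statistics slightly less
correlated between adjacent windows than in real genomes.

Sweeps are imposed post hoc by haplotype overwriting, which gives exact
truth labels at zero forward-simulation cost: within the interval, every
modern dog chromosome is replaced by the site-wise majority haplotype,
except a `residual` fraction of sites left untouched (fixed-haplotype
mode) or a `residual` fraction of chromosomes left untouched
(frequency-raise mode). Ancient samples (two by default) are extra dog
chromosomes drawn at time 0 — no extra drift or damage is modelled —
and are reserved in neutral form: the carrier policy then makes them
homozygous for the swept haplotype (`ancientCarrier = TRUE`) or for a
maximally divergent alternative that carries the non-swept allele
wherever the pre-sweep cohort held one (`FALSE`). A single sampled
pre-sweep haplotype would coincide with the swept majority over long
tracts and be invisible to ΔH~P~ there; the maximal-divergence
construction makes the veto deterministic (ΔH~P~ ≈ 0.085 in affected
windows regardless of SNP count), at the cost of being a composite
rather than a sampled haplotype.

Depth tracks are generated at window level (not read level):
`meanDepth × (CN/2) × gcBias(GC) × (1 + N(0, noiseSd))`, truncated at
zero, with GC fractions drawn per window from a Beta distribution
centred at 0.42 and the default bias curve peaking at GC 0.45 with
factor range [0.6, 1.1]. Planted copy-number differences draw each
sample's copy number once per interval from its population's
distribution. What passing tests show about real data is therefore
limited: mapping artifacts, paralog collapse, aDNA damage, genotype
error and reference bias are all absent from the generator, so the
pipeline's operating characteristics on real cohorts must still be
established with real controls.

## Numerical and degenerate-case choices

- Percentiles use linear interpolation (R's type 7) everywhere, so
  thresholds are reproducible to machine precision from stored values.
- Z-transforms use the sample standard deviation (N−1) and fail loudly
  on zero variance rather than emitting NaN.
- Calibrated thresholds are strict exceedances ("exceed" → `>`); a
  window exactly at the threshold does not pass.
- "Within 50 kb" merging means inter-window gap ≤ 50 kb; `maxGap = 0`
  joins overlapping or book-ended windows only.
- Windows with insufficient support (SNPs or scored grid points) carry
  `NA` values and flags rather than being silently dropped, so support
  accounting survives to the manifest.
- The MAF filter removes sites with minor-allele count strictly below 3
  of the 106 modern chromosomes (frequency 0.028); ancient samples are
  excluded from it and from p₁/p₂ — they enter only through ΔH~P~.
- X-nonPAR sites with any male heterozygote are removed; male genotypes
  there are stored as single-chromosome dosages.
- Reference-allele ties: wherever a major allele must be chosen from a
  50/50 count, the reference allele wins, consistently across the
  frequency table and the sweep generator.

## Problem sizes used by the shipped tests

The test suite and `scripts/acceptance.R` run the full cascade at desk
scale, as the package's own choice of test size: threshold calibration
pools 8–10 neutral replicates of a 25-Mb single-chromosome genome
(roughly 40,000 post-filter SNPs per replicate); sweep-recovery cohorts
plant ten 400-kb sweeps (residual diversity 2%) on 25 Mb; the
non-carrier veto is checked on ten constructed 80-kb sweeps; the
copy-number scan uses 3-kb windows on 1.5-Mb genomes over 10–20 seeds.
At these sizes the binomial confidence envelopes in the calibration
checks are necessarily wide; the full-scale published thresholds are
approximated but not reproduced exactly (F~ST~ and H~P~ within ~10%,
XP-CLR ~20% low, as discussed above).

## Known limitations

- The published multi-lineage demography is supported by the config
  format but its parameter values are not bundled; the example config in
  `inst/extdata/` is synthetic and labelled as such.
- The XP-CLR score scale is implementation-defined; compare scores only
  against thresholds calibrated by this implementation, never against
  scores from other XP-CLR software.
- The block coalescent is not a recombination-accurate simulator; LD-
  sensitive statistics beyond windowed scans should not be validated
  against it.
- Depth simulation is windowed and Gaussian; it cannot exercise
  QuicK-mer/fastCN-style read-level normalization, only the
  normalization/statistics layer this package implements.
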