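---
title: "Models and methods behind magicmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind magicmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`magicmap` simulates and analyses eight-way MAGIC populations: eight
inbred founders crossed through a funnel (2-way, 4-way, 8-way F1) and
then selfed by single-seed descent, so that each line is a nearly
homozygous mosaic of founder genomes.  This vignette explains the
models, the defaults and why they were chosen, the numerical choices,
and what the synthetic test bed does and does not demonstrate.

## The forward simulator

**Founder panel.**  Eight founders in two subspecies-like groups (four
"Xian-like", four "Geng-like").  Marker allele frequencies follow a
Balding–Nichols model: ancestral frequency p ~ U(0.15, 0.85) per
marker, group frequencies drawn from Beta(p(1−F)/F, (1−p)(1−F)/F) with
F = `divergence`.  The default F = 0.55 matches the published
population-differentiation statistic between the indica and japonica
rice landrace groups, which the two founder groups emulate.
Monomorphic markers are dropped.  The default marker density of 5
markers / 10 kb corresponds to resequencing-grade SNP density.

**Meiosis.**  Crossover counts per chromosome are Poisson with mean
equal to the Morgan length; positions are uniform on the genetic scale
and mapped to bp by a uniform cM/Mb rate (default 4 cM/Mb, a
rice-typical genome-wide average).  No interference and no obligate
chiasma: these match the Haldane assumptions used by the downstream
mapping functions, and at the map lengths used the obligate-chiasma
correction is negligible.  Coincident crossover pairs cancel.

**Selection.**  Two gamete-level modes model hybrid-incompatibility
systems: a *pollen killer* eliminates male gametes carrying the
sensitive allele in heterozygous plants with probability s, and a
*killer–protector* system does the same on the female side.  `carriers`
names the founders whose allele is safe; heterozygosity is evaluated at
the safe/victim class level, so two different safe founders do not form
a killing heterozygote.  Selfing a heterozygote at s = 1 gives offspring
1/2 safe-homozygote and 1/2 heterozygote — victim allele frequency 1/4 —
and the tests verify the simulator against an exact single-locus
genotype-frequency recursion through the full funnel.  *Zygote
viability* selection targets a multi-locus functional combination (the
model for photoperiod-gene combinations whose carriers fail to set
seed): during single-seed descent an affected plant is discarded with
probability s and replaced by a resampled selfed sibling, so line
number is preserved, mimicking a breeder advancing a different seed.

**Trait model.**  Each QTL carries one additive effect per founder
allele (days); heterozygotes get the mean of their two founder effects
(the analyses downstream estimate additive effects only); environments
add fixed offsets; residuals are Gaussian.  The demo configuration uses
one major and two minor QTLs on three 30-Mb chromosomes — enough to
exercise both arms of the scan machinery — which yields a broad-sense
heritability around 70–80%.  A real heading-date architecture has many
more minor QTLs and substantially higher heritability; the demo trait
is deliberately sparse, and quantities that depend on the full
architecture (total PVE, H²) are therefore not comparable to field
values.

**RNG.**  Every stochastic entry point takes a `seed`; the pipeline
seeds once per run and records the seed and a config hash in every
output file's provenance header.

## Ancestry inference

The HMM has one state per founder (K = 8).  Lines at F6 are ~98.4%
homozygous, so a diploid 36-state model buys little; residual
heterozygous calls are absorbed by the `e_het` emission term, whose
default (0.026) matches the heterozygous call fraction observed in
deep-resequenced populations of this design.  Emissions for founder
allele a: P(obs = 2a) = 1 − e_hom − e_het, P(het) = e_het,
P(opposite hom) = e_hom (default 0.005); missing observations are
uninformative.  Transitions follow a junction process of intensity
`lambda_bp` (default 3e-7/bp, the junction density of an F6 eight-way
line at ~4 cM/Mb): over distance d, theta = 1 − exp(−lambda d) of the
ancestry "mixes" uniformly over the K states.  `estimate_lambda()`
re-estimates the intensity from a decode for self-consistency.

Decoding is Viterbi (bins need hard labels); forward–backward
posteriors are kept for QC and for deciding which neighbour absorbs a
filtered segment.  Ties break toward the lower founder index.  Run
boundaries sit at the floor of the flanking marker-interval midpoint;
segments shorter than `min_seg_bp` (default 5000 bp, the scale of the
smallest reported population bins) are merged into the neighbour with
the higher flanking posterior.  Both decoders are property-tested
against exhaustive path enumeration on small instances.

One behaviour worth knowing: on observations that actually contain
miscalls, *raising* the assumed `e_hom` can raise the decoded path's
mean posterior, because the errors are explained better.  Only on
error-free data is decoding confidence monotone non-increasing in
`e_hom`; the test suite asserts the property there.

## Bin map and genetic map

Bin boundaries are the union of all lines' segment boundaries; bins
shorter than `min_bin_bp` merge into the shorter neighbour (ties left),
which minimises boundary displacement.  A line's label at a bin is the
ancestry at the bin midpoint — identical to a per-bp majority vote
except at merged slivers (the tests keep the bp-level oracle).
Adjacent-bin label-change frequencies convert to map distance by
Haldane's d = −50 ln(1 − 2r) cM after dividing by `expansion_factor`.
The population accumulates recombination over three outcross and g
selfing generations, so the observed breakpoint frequency is an
*expanded* recombination fraction; no closed-form correction for this
design is assumed, the factor defaults to 1 (population-scale map) and
can be set or estimated by simulation.

## QTL scans

**GWAS** is ordinary least squares of line means on SNP dosage.  No
kinship mixed model and, by default, no PC covariates: the design
produces weak structure (the PCA diagnostic in `structure_diagnostics()`
shows this directly), and the genomic-inflation factor is reported so
the user can check.  The Benjamini–Hochberg step-up over all tested
SNPs gives the significance cutoff; significant SNPs within 600 kb
(about the short end of the population's LD-decay range) clump into
loci led by the smallest p.

**Linkage scan** works on the bin founder-factor.  Cofactors are chosen
by forward–backward stepwise F-tests (p_in = 0.001, p_out = 0.002);
when testing a bin, cofactors within 10 Mb of it are excluded and the
phenotype is adjusted by the rest (ICIM's background control).  LOD =
(n/2) log10(RSS0/RSS1), the Gaussian-equivalence form, which is
deterministic and exactly affine-invariant.  Thresholds come from
permuting the phenotype across lines and taking the empirical 95th
percentile of the genome-wide maximum LOD; the permutation scan is
cofactor-free by default (under the null the cofactor set is empty in
expectation, and this keeps 1000 permutations cheap and vectorised).
QTLs are maximal runs of supra-threshold bins; support intervals extend
outward from the peak until LOD drops 1.5 (a standard convention for
line crosses); PVE is the single-locus R² of the
lead-bin factor model; the additive effect range is half the spread of
founder group means with at least `min_group_n = 10` lines.  Offset
distance to a known gene is 0 on overlap, else the coordinate gap
between facing edges (an abutting gene is 1 bp away), plus the count
of whole bins strictly between.

## Genome scans

Segregation distortion: per-bin Pearson chi-square of founder counts
against equal n/8 shares (df = 7), Bonferroni over bins, significant
bins merged across gaps of at most one non-significant bin.  The test
choice is a design decision; at the population sizes involved the
chi-square approximation is comfortable.  Recombination landscape:
fixed 1-Mb windows, population breakpoint counts tested two-sided
against the genome-wide Poisson rate with BH correction (q < 0.05);
upper tail = hotspot, lower = suppression.  A Poisson test was chosen
over permutation for determinism; the partial last window is
rate-normalised by its true length.

## Allele ranking and heritability

Founder group means at the lead bin (gene-local ancestry would also be
defensible; lead-bin ancestry is what a mapping study reports), pooled
MSE from the one-way ANOVA.  Duncan's multiple range test (matching
field practice for these comparisons; Tukey would be more conservative)
uses least significant ranges q(1 − (1−α)^(p−1); p, df)·sqrt(MSE/n_h)
with the harmonic-mean group size for unbalanced groups.  Letters come
from maximal non-significant stretches of the descending means, so two
groups share a letter iff their range test is non-significant; the
suite cross-checks the letters against an independent implementation
that computes the studentized-range CDF by numerical integration.
Effect levels = distinct letters in the display (a, ab, b collapses to
2 levels, the conservative reading); labels run none (smallest mean)
through weak/intermediate to strong.  Broad-sense heritability uses
the line × environment ANOVA: σ²G = (MS_line − MS_e)/r,
H² = 100·σ²G/(σ²G + σ²e/r), negative components floored at zero.

## Problem sizes and what the tests show

The test suite runs everything at desk scale: the neutral-expectation
checks use 500 lines on three 30-Mb chromosomes; ancestry recovery uses
20 lines at 5 markers/10 kb with 0.5% error (≥99% of the genome gets
the true founder, counting either haplotype at residually heterozygous
positions); scan calibration uses 200 null phenotypes on a fixed
150-line bin matrix with 100-permutation thresholds; power uses 20
replicates of a 300-line, 20-Mb population with an 8%- or 2%-PVE QTL
planted.  These sizes were chosen so the whole suite runs in minutes
while keeping Monte-Carlo error well inside the 3-SE bands being
asserted.

What passing does **not** show: the simulator has no linkage-map
heterogeneity (uniform cM/Mb, so real centromeric suppression is only
emulated when seeded), no crossover interference, no
genotype-by-environment interaction, no epistasis, and sequence-level
artefacts (mapping bias, SVs, inversions) are out of scope.  Counts
that depend on the real data — total bins, loci, QTLs, map length —
scale with population size and genome length and are not reproduced at
desk scale.  On small genomes the whole chromosome can sit in high LD,
making LOD profiles plateau-like; lead bins then wander within the
plateau, which is the expected behaviour, not a defect.
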