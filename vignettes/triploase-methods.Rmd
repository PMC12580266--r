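---
title: "Methods: parent-of-origin analysis in reciprocal triploid hybrids"
author: "triploase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parent-of-origin analysis in reciprocal triploid hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Triploid hybrids from reciprocal diploid x tetraploid crosses carry an
unbalanced 2:1 parental genome ratio, and molecular differences between a
paternal-excess triploid (2x mother x 4x father) and its maternal-excess
reciprocal (4x mother x 2x father) cannot be explained by allele sequence —
the two crosses have the same alleles. Such differences are parent-of-origin
effects (POE). `triploase` implements a complete desk-scale version of the
analysis chain used to dissect POE in such series: factorial differential
expression separating POE from ploidy and hybridity, a dosage-aware
allele-specific expression (ASE) test, reciprocal-cross imprinting calls,
allele-specific methylation (ASM) statistics, and diurnal expression
summaries — all exercised end to end on a synthetic-data generator with
planted ground truth.

The central design object is the cross design: every sample belongs to a
group, every group has a maternal and a paternal parental genotype with a
known ploidy, and group classes (parental self, 2x/4x hybrid,
maternal-/paternal-excess triploid) are derived from those ploidies, never
typed in by hand. Allele labels in data files are always genotypes
(e.g. L2/L4); which allele is maternal is resolved per cross through the
design. This separation is deliberate: the same genotype allele is maternal
in one reciprocal cross and paternal in the other, and that flip is what
lets the pipeline distinguish parent-of-origin effects from cis
(sequence-attached) effects.

## The dosage null and the ASE test

In a triploid, the tetraploid parent contributed two of the three genome
copies, so under no allelic regulation its allele should generate 2/3 of
allelic reads; balanced crosses expect 1/2. The expected fraction of an
allele is its parent's contributed copies over the total,
`ploidy_parent / (ploidy_maternal + ploidy_paternal)`.

Each informative SNP is tested with a two-sided exact binomial test of the
pooled maternal read count against this null fraction. Two-sidedness uses
the minimum-likelihood convention (the p-value sums the probabilities of
every outcome no more likely than the observed one), so an observation at
the modal expectation — e.g. 20 vs 10 reads under 2/3 — yields p = 1
exactly. A relative tolerance of 1e-7 on the "no more likely" comparison is
part of the definition: without it, floating-point representation breaks
exact pmf ties (most visibly at f = 1/2) and the p-value becomes
implementation-dependent.

Aggregation to genes follows the conventional procedure: biological
replicates are pooled by read summation per SNP (the 10-read filter is
applied to the pooled count, which is the natural reading of a filter
"across all biological replicates"); SNPs below 10 pooled reads are
dropped; Benjamini–Hochberg correction is applied across all tested SNPs
of a cross (a per-gene scope is available — the choice is exposed because
the convention varies between studies); a gene is a significant ASE gene
if any of its SNPs has FDR < 0.05. The gene's direction comes from its
pooled counts rather than its best SNP, and genes whose significant SNPs
disagree in direction are reported as `conflicting` and never counted as
biased — single-SNP directions at modest depth are noisy, and a
pooled-direction rule is the most defensible tie-break.

### Imprinting versus cis bias

A gene is called PEG (paternally expressed imprinted gene) only when it is
significantly paternally biased in **both** reciprocal crosses, MEG when
maternally biased in both. Because the maternal genotype flips between
reciprocal crosses, a gene favouring the same *genotype* allele in both
crosses (maternal in one, paternal in the other) is `cis_biased` — the
confounder the two-cross criterion exists to remove — and is reported
separately, never as imprinted. The caller reports all candidates with
their per-cross evidence instead of enforcing any expected count.

## The differential-expression substitute

The pipeline needs a defined, dependency-light two-group test rather than a
re-implementation of any published framework. It uses a negative-binomial
Wald test: per-gene method-of-moments dispersion pooled across the two
groups (floored at 1e-8 because three replicates routinely produce negative
moment estimates), delta-method standard errors on the difference of log
group means, and the conventional significance rule |log2FC| >= 1 and raw
p < 0.05 (no multiple-testing correction, matching the thresholds this kind
of analysis reports). The fold change is computed as a difference of logs so
that swapping the groups flips its sign exactly; a pseudocount of 1 enters
only when a group mean is zero. This estimator is anticonservative in p
near zero counts, but the |log2FC| >= 1 gate dominates the decision at
realistic depths: under the null simulation the significant fraction stays
well below the 7% envelope asserted in the tests.

Normalization defaults to median-of-ratios (geometric-mean reference over
genes observed in all samples, per-sample median ratio), with simple totals
available. Median-of-ratios assumes most genes are unchanged; the synthetic
defaults plant 29% changed genes, which leaves a visible but harmless bias
in the triploid size factors (the suite's calibration checks pass with it).

Factorial contrasts: POE (paternal- vs maternal-excess triploids), ploidy
(all triploids vs diploid selfs and vs tetraploid selfs), hybridity
(same-ploidy hybrids vs selfs), and an optional genetic-distance contrast
driven by a user-supplied group map, since no rule can derive "close" vs
"distant" parents from ploidies. Contrasts pool all samples per side by
default; a per-pair mode (test every group pair, union the calls) is
available because published DEG counts rarely state which was used. Factors
are ranked by their largest contrast's DEG count, ties broken
alphabetically (case-insensitive).

## Clustering

Profiles are z-scored per gene over **group means** (one value per group) —
the x-axis of the usual cluster trend figures; replicate-level profiles are
available behind a flag. Constant genes are flagged, given all-zero
profiles, and excluded from clustering. Fuzzy c-means follows the standard
alternating updates with Euclidean distance, fuzzifier m = 2, c = 5 and
membership threshold 0.7 as defaults; initialization is k-means++-style
seeding from an explicit seed, because the published parameter set omits
initialization and reproducibility demands one. A point at exactly zero
distance from a center takes membership 1 there. The objective
`sum u^m d^2` is recorded per iteration and asserted non-increasing in the
tests. Convergence is the largest membership change < 1e-6, capped at 500
iterations. The vigor-relevant cluster is chosen as the one whose center
attains its maximum at the paternal-excess group; its members are split
into 10 sub-clusters with Lloyd's k-means (best of 10 seeded restarts).

One honest caveat the synthetic data makes visible: planted DEGs have only
a handful of distinct profile shapes, so c = 5 places near-duplicate
centers on the dominant shape and memberships split below the 0.7
threshold. The analysis therefore sub-clusters the peak cluster's argmax
members and reports the threshold-passing count alongside. Real data, with
a continuum of profiles, is exactly the situation the threshold was
designed for.

## Allele-specific methylation

Per-cytosine levels are methylated/total reads, computed only at >= 5 reads
after pooling replicates by read summation (the same pooling convention as
the ASE stage). Region means are **unweighted** means of qualifying site
levels — weighting by coverage would let deep sites dominate and change the
statistic's meaning from "average cytosine" to "average read". Regions are
strand-aware: 2-kb upstream flank, TSS–TTS body, 2-kb downstream flank,
with minus-strand genes oriented 5'→3' on load. A region needs at least 3
qualifying sites per allele (`min_sites = 3`); no published site floor
exists, but without one single-cytosine regions dominate the ASM
distribution tails. CG-dyad strand collapsing is off by default and
toggleable.

The ASM difference is |mean(L2) − mean(L4)| per gene region and context.
Reciprocal crosses are compared with a two-sided Wilcoxon rank-sum test —
unpaired by default, since the published comparison is named rank-sum; a
gene-paired signed-rank mode exists. Exact p-values are used up to 25
values per side, the tie-corrected normal approximation beyond.
Significance is annotated with the display tiers used for this comparison,
including the dagger at p < 0.1.

Metagene profiles bin the flanks at fixed width (2000/20 bp by default) and
rescale the body into 40 proportional bins; per gene, site levels are
averaged within bins, then bins are averaged unweighted across genes. The
gbM–expression association is a Spearman correlation between the per-gene
paternal-minus-maternal body-CG difference and the paternal allelic
expression fraction, over genes with both measures; it errors below 3 pairs
and reports NA when either measure is constant.

## Diurnal summaries

Relative expression follows 2^-ddCt. With only four timepoints (ZT0/6/12/18)
in one cycle, cosinor fitting would be parameter-starved, so the summaries
are argmax/argmin of per-ZT replicate means, amplitude = max − min of those
means, and relative amplitude = amplitude/mean (scale-invariant); ties break
toward the earlier ZT and are flagged. Per-timepoint reciprocal comparisons
use a two-sided Welch t-test (three biological replicates with no variance
homogeneity guarantee; a rank-sum alternative is exposed) with the usual
star tiers.

## What the generator emulates — and what it does not

The generator reproduces the study's structure at desk scale: 10 groups
(4 parental selfs, reciprocal 2x, 3x(m)/3x(p), and 4x hybrids) x 3
replicates; negative-binomial counts (2000 genes, ~1e6 reads/sample,
dispersion 0.05, log-normal baseline spread); Poisson(3) informative SNPs
per gene at Poisson(30) reads per SNP per sample; allele-resolved
methylomes with context-specific baselines (body CG 0.30, flanks 0.15; CHG
~0.1; CHH ~0.05, Poisson(10) coverage); cosinor-shaped diurnal series with
additive replicate noise (SD 0.1).

Planted truth drives every downstream test: 400/150/30 POE/ploidy/hybridity
genes at log2 effects 3/2/2; 10 PEGs and 10 cis genes at allelic fraction
0.9; 100 maternal- and 20 paternal-biased genes **per cross direction**
(distinct sets per direction, so ordinary bias never mimics the both-cross
consistency that defines imprinting); 50 gene-body-CG-asymmetry genes with
a +0.3 paternal offset, coupled to a paternal expression bias so the
gbM–expression association has signal.

Three generator choices deserve explanation:

* **POE effects are planted antisymmetrically** (x2^(lfc/2) in
  paternal-excess, x2^(-lfc/2) in maternal-excess groups). Planting the
  whole effect on one side would shift the pooled-triploid mean and leak a
  parent-of-origin signal into the ploidy contrasts, corrupting the
  factorial ranking the design is meant to separate.
* **Allelic depth is independent of the gene's expression level.** The ASE
  test consumes only allelic counts, so coupling them to the count matrix
  would add machinery without exercising anything new.
* **PEG planting is parent-attached, cis planting genotype-attached** —
  they are the positive and negative controls for the imprinting caller.

Features of real data the generator does **not** emulate: mapping bias at
SNPs (the 2:1 null is taken at face value), correlation between SNPs of a
gene beyond shared truth, profile-shape diversity among DEGs (see the
clustering caveat), batch effects, and count–methylation coupling beyond
the planted gbM set. Passing tests therefore demonstrate correctness of the
statistics under the stated models, not robustness to those artefacts; the
mapping-bias caveat in particular is the reason real analyses should
inspect per-replicate concordance, which the ASE stage reports as a
diagnostic.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations for a
single CPU: the exact-binomial oracle sweep covers all counts at n <= 60
for null fractions {1/3, 1/2, 2/3}; ASE null calibration uses ~10,000 SNPs
at 30 pooled reads; imprinting discrimination uses 50 planted PEGs + 50 cis
genes + 900 null genes at 50 reads/SNP/replicate; the factorial ranking is
repeated over 50–100 seeds at the full 2000-gene design; the Wilcoxon null
uniformity check uses 500 replicates of 40 values per side. Degenerate
inputs follow documented policies rather than erroring where a value is
representable: zero-total SNPs are excluded, both-zero genes get log2FC 0
and no call, constant profiles are flagged, sub-threshold regions are NA
and excluded from tests.

## Reproducibility

Every stochastic function takes its seed from `sim_params()`; a fixed seed
gives byte-identical outputs, which the suite asserts on full demo runs.
The demo writes a run manifest (seed, sizes, package and R versions) next
to its outputs, and all result tables are plain TSV with stable column
order so diffs are deterministic.
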