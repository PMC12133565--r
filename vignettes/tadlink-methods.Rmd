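---
title: "TAD-constrained integration of chromatin accessibility and gene expression"
author: "tadlink maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TAD-constrained integration of chromatin accessibility and gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadlink)
```

# The problem

ATAC-seq identifies open chromatin — candidate regulatory elements — and
RNA-seq measures gene expression, but neither says which element
regulates which gene. Linear proximity is a poor guide because enhancers
act over long ranges, yet regulatory contacts rarely cross the
boundaries of topologically associating domains (TADs), the
self-interacting blocks inferred from Hi-C. `tadlink` operationalizes
that constraint: it correlates each peak's accessibility with each
gene's expression across samples, but only for peak–gene pairs whose
anchors (peak midpoint, gene TSS) fall inside the same TAD. A
significant positive correlation reads as "chromatin opening at this
element tracks with higher expression of this gene"; a negative one as
the opposite. The motivating study design is a two-genotype mouse tumor
comparison with four biological replicates per genotype, profiled by
ATAC-seq and RNA-seq in parallel; TADs are consumed as an input
partition (from public Hi-C), never called here.

# The pipeline

`runPipeline()` executes, in order: format parsing; per-group consensus
peak construction and shared/unique (Venn) classification; size-factor
and variance-stabilizing normalization of both count matrices; PCA of
accessibility; negative-binomial differential expression with
Benjamini–Hochberg correction; genomic-context annotation of peaks; TAD
assignment, within-TAD pair enumeration and Pearson linking; link
summaries; and (optionally) motif enrichment of group-unique promoter
peaks. Each stage is an exported function usable on its own, and each
writes plain-text tables so every reported count can be recomputed.

## Coordinates

Files keep their native conventions — BED and narrowPeak are 0-based
half-open, GTF is 1-based closed — and everything is converted at the
I/O boundary into `GRanges`, which is 1-based closed throughout
Bioconductor. Reader/writer pairs are tested to be mutually inverse at
the byte level, which is what actually guards against off-by-one drift.
Two corollaries of the half-open file convention survive inside the
package: intervals that merely touch (end of one equals start of the
next) share no base and are *not* merged, and an anchor lying exactly on
a shared TAD boundary belongs to the downstream TAD.

## Consensus peaks and the Venn unit

Replicate peak calls are union-merged (>= 1 shared bp to merge) and a
merged region is kept when peaks from at least `min_samples` distinct
replicates overlap it (default 2, the standard replicate-support
heuristic). For the shared/unique comparison of two groups the counting
unit is the merged region of the union of both consensus sets, labelled
by which groups cover it. This makes the three categories disjoint, tile
the union exactly, and count a shared region once — the one unambiguous
unit for a Venn of region sets.

## Normalization

Size factors are median-of-ratios: per sample, the median over
all-positive features of the count divided by the feature's geometric
mean, rescaled to geometric mean one. Two variance-stabilizing
transforms are provided: `log2p1`, `y = log2(x/s + 1)` (the default,
monotone and parameter-free), and `asinh_nb`,
`y = (2/sqrt(a)) * asinh(sqrt(a x/s))` with `a` a common moment-based NB
dispersion — the classical stabilizer for NB counts, linear in `log x`
for large counts. Both map zero to zero. A known limitation inherited
from median-of-ratios: when a large, one-directional fraction of
features is differential, factors absorb part of the signal and all fold
changes compress slightly; at the ~10% differential fraction typical of
these designs the effect is negligible.

## Differential testing

Per feature, normalized group means are compared as
`lfc = log2((muB + c)/(muA + c))` with pseudocount `c = 0.5` (finite for
zero groups). The NB dispersion is estimated by moments pooled across
the two groups, `a = ((varA - muA) + (varB - muB)) / (muA^2 + muB^2)`,
floored at `1e-8` (sub-Poisson variance is treated as Poisson) and
multiplied by `n/(n - 2)` to offset the estimator's small-sample
downward bias. The delta-method standard error uses the NB variance
`mu + a mu^2`, and the Wald statistic is referred to a t distribution
with `n - 2` degrees of freedom. The t reference (rather than a normal)
is deliberate: with four replicates per group the dispersion is
estimated from six residual degrees of freedom, and a normal reference
is measurably anticonservative (empirical type-I error near 0.12 at
nominal 0.05), while the t reference keeps the test inside the 0.03–0.07
calibration band the package tests enforce. Calls use the published
convention: adjusted p < 0.05 and |LFC| >= 1, both configurable
(`alpha_de`, `lfc_min`). No dispersion shrinkage toward a trend and no
lfc shrinkage are attempted — those belong to dedicated DE packages; the
aim here is a transparent, calibrated test.

The test suite's power check plants lfc = 2 features at mean 100 with
dispersion 0.05 — a realistic gene-wise dispersion for high-count
features in inbred-mouse replicate designs. At a biological-replicate
dispersion of 0.4 no test of any construction reaches 80% power in a
4-vs-4 design (the oracle Wald statistic itself sits near 3), so the
power contract is meaningful only in the low-dispersion regime.

## TAD-constrained linking

Peaks anchor at their midpoint (the summit is available when recorded;
the midpoint always exists), genes at their TSS. Pairs are the Cartesian
product of assigned peaks and genes within each TAD; elements outside
every TAD are excluded and counted. Pearson correlation is computed
across all samples pooled — the association of interest is across-sample
covariation, which needs no group labels, and pooling doubles the
effective n. Significance defaults to the raw p at `alpha_corr = 0.05`,
mirroring the raw-p convention of the upstream analysis this pipeline
standardizes ("significant correlations (p < 0.05)"); `corr_adjust =
"BH"` switches to FDR-adjusted calling. One upstream figure caption
prints a correlation threshold of 0.5 where the running text uses 0.05 —
almost certainly a typo, but not ours to resolve silently: the threshold
is an explicit parameter everywhere it is used.

The two-sided p comes from `t = r sqrt(n-2)/sqrt(1-r^2)` on `n - 2`
degrees of freedom. Numerically perfect correlations are reported as
`p = 0` with a `perfect` flag rather than floating-point noise, and
zero-variance members drop the pair with reason code `zero_variance`.
Note the t-based p is an unconditional reference: the exhaustive
permutation null of a *specific* small-n pair is conditional on its
values and scatters around it (at n = 6, individual Gaussian pairs
deviate by up to ~0.12 even though the mean discrepancy is ~0.02), which
is why the package's oracle tests bound the typical, not the worst-case,
disagreement.

## Peak annotation

Each peak is classified at its anchor with precedence promoter > TTS >
exon > intron > intergenic. The promoter window is −1000/+100 bp around
the TSS in transcription orientation and the TTS window ±100 bp —
Homer-style defaults, configurable. Ties between equidistant genes break
to the lexicographically smaller gene id, making annotation
deterministic.

## Motif enrichment

PWMs are read from JASPAR text; counts become probabilities with a
background-split pseudocount (each column gains `4 * pseudocount * bg_i`
per base — with the default 0.8 and a uniform background, 0.8 per cell).
Scores are log2 odds against the background, in bits. The scan threshold
is principled rather than ad hoc: the exact distribution of the score of
a random background L-mer is computed by dynamic programming over
per-column score distributions discretized at 0.01 bits, and the
threshold is the smallest achievable score whose tail probability is at
most the target (default 1e-4). When no achievable score satisfies the
target — very short or nearly flat matrices — the maximal achievable
score is returned. Both strands are scanned; windows containing N are
skipped. Enrichment is Homer's classic statistic: sequence-level
presence/absence and a one-sided hypergeometric upper tail for the
target set against the pooled target+background universe, with a
GC-matched, length-matched, target-disjoint background sampler (±0.05 GC
tolerance, seeded rejection sampling with a bounded retry budget).
Zero-order background only; de novo discovery and ZOOPS binomial
scoring are out of scope.

The NFAT:AP1 composite matrix shipped at
`inst/extdata/nfat_ap1_synthetic.jaspar` is a synthetic stand-in built
from the published consensus (NFAT TTTCC core, spacer, AP-1 TGASTCA) —
the genuine library matrix is external and the package accepts any PWM.

# The synthetic-data generator

Because the study's real sequencing data cannot be reprocessed at desk
scale, every stage is validated on synthetic data with a planted ground
truth. `simConfig()` defaults define the emulated conditions: two groups
of four replicates; 2 chromosomes × 1 Mb of i.i.d. DNA at GC 0.41
(mouse-like); 20 TADs tiling the chromosomes; 300 genes and 1000 peaks
spread round-robin across TADs (so every TAD is populated) with random
positions inside; NB counts with dispersion 0.05 and log-uniform means
in 20–2000; 10% differential genes at lfc 2 (group-B mean multiplied by
`2^lfc`); 20% group-unique peaks (the absent group's mean divided by
`2^lfc`); 1% of within-TAD pairs planted as links at target |r| = 0.9
with 20% negative; motif instances written into group-B-unique peaks at
rate 0.6 versus 0.05 elsewhere; log-normal library factors (sd 0.2); and
±10 bp per-sample peak-boundary jitter. Every value is a single
`simConfig()` argument and every byte of output is reproducible from the
seed.

Planted correlations use a shared log-normal latent factor rather than a
Gaussian copula: each linked pair draws per-sample `z ~ N(0, s2)` and
multiplies both members' NB means by `exp(z - s2/2)` (the peak by
`exp(-z - s2/2)` for negative links), keeping counts marginally NB-like
and making sign inversion trivial. The latent variance is calibrated
through the delta-method noise variances `v = 1/mu + a` of the two
members: `s2 = r/(1-r) * sqrt(vp * vg)` yields expected Pearson r on VST
values close to the target; linked features draw base means of at least
100 so count noise cannot wash the correlation out. Planted links avoid
group-unique peaks and differential genes, and each peak or gene carries
at most one link, so every planted effect is attributable to a single
cause. The generator's statistical contracts — link-r calibration within
0.1, lfc recovery within 0.25 at mean >= 100, >= 99% consensus recovery
at <= 10 bp jitter, TSS-in-TAD by construction — are themselves tested,
since the analysis-level acceptance checks depend on them.

What the generator does not emulate: read-level artifacts (Tn5 bias,
fragment-length structure, mappability), overdispersed peak-width
distributions, correlated gene programs, batch effects, or Hi-C contact
decay. Passing tests therefore demonstrate the statistical machinery is
correct and calibrated under the stated model, not that the pipeline is
robust to every artifact of real sequencing data.

# Validation design and problem sizes

The acceptance suite runs, at these scales: link recovery on a dataset
built with one peak and one gene per TAD (2200 TADs) so the pair
universe is exactly 200 planted links plus 2000 null pairs — recall
>= 0.8, sign accuracy >= 0.95, null false-positive rate inside the
binomial 95% CI of 0.05; NB calibration on 2000 null features
(dispersion 0.4) and 200 planted features (lfc 2, mean 100, dispersion
0.05) — type-I error in [0.03, 0.07], power >= 0.8 at adjusted p < 0.05;
t-vs-permutation agreement at n = 6 over 100 pairs on the mean
discrepancy; exact BH equivalence on 1000 random vectors; per-base
painting equivalence for the peak algebra on 200 toy genomes; DP-vs-
enumeration equality for motif score tails up to L = 6, planted-motif
enrichment below 1e-6, and a 150-run null motif simulation inside the
binomial CI; byte-level determinism of two pipeline runs; and full
reader/writer round trips. `scripts/acceptance.R` recomputes the
statistical quantities from scratch under a caller-supplied seed.

# Known limitations

* Correlation on eight pooled samples has limited power below |r| ~ 0.7
  and the raw-p convention does not control FDR over thousands of pairs;
  the BH switch exists for stricter analyses.
* Median-of-ratios factors compress fold changes under heavily
  one-directional differential signal.
* The moment dispersion estimator is noisy at n = 4 + 4; the t reference
  and bias correction keep it calibrated, at a small cost in power
  relative to shrinkage-based engines.
* Motif enrichment treats sequences as exchangeable presence/absence
  units; clustered hits within one sequence carry no extra weight.
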