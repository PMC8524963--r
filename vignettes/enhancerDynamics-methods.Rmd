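---
title: "Methods: deriving critical regions and calling differential enhancer activity"
author: "enhancerDynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving critical regions and calling differential enhancer activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical procedures it
implements, the assumptions behind them, and the design choices made where
several constructions were defensible. Nothing here reports an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## Coordinates and interval algebra

All coordinates are BED convention — 0-based, half-open `[start, end)` —
and conversion happens exactly once, at the reader boundary (`readBed()`
has a `oneBased` flag for catalogs distributed with 1-based inclusive
coordinates; only the start shifts). Chromosome names match by exact
string equality: silent `chr1`/`1` aliasing corrupts overlap counts, so no
aliasing is ever attempted. Sorting is lexicographic by chromosome, then
start, then end, with stable ties. Interval algebra (merge, coverage
depth, pairwise intersection) is delegated to `IRanges`/`GenomicRanges`;
the test suite re-derives every operation against per-base brute-force
oracles, so the delegation is verified, not assumed. Two abutting
half-open intervals merge (gap 0) but do not intersect — both semantics
are asserted explicitly.

## Putative critical regions

The derivation assumes that independently produced enhancer catalogs make
correlated calls around genuinely functional sequence, so the *maximal
source-overlap depth* sub-region of a cluster is the best-supported
candidate:

1. records identical in (chrom, start, end, source) are collapsed;
   identical coordinates from *different* sources are kept, because they
   are the evidence of interest (they contribute depth 2);
2. per source, records are unioned first, so two overlapping calls from
   one database contribute depth 1 — depth counts *distinct sources*;
3. within each merged cluster the contiguous run(s) attaining the maximal
   depth become candidates when that depth is ≥ 2; several disjoint
   maximal runs each become an independent candidate (all equally
   supported). Clusters supported by a single source contribute the
   single-source region itself — exclusivity to one catalog is not
   evidence of absence;
4. candidates shorter than 50 bp or longer than 1000 bp are dropped
   (region boundaries below the jitter scale of the catalogs are not
   meaningful; very long regions are usually merged artifacts);
5. candidates overlapping a strand-oriented promoter window — 2000 bp
   upstream to 1000 bp downstream of any annotated TSS — are removed.
   Upstream/downstream are meaningless without strand, so the window
   reflects around minus-strand TSSs, and unstranded gene records are a
   validation error rather than a silent guess;
6. candidates with fewer than 10 reads in fewer than 2 samples of the
   accompanying count matrix are removed ("retained iff sufficiently
   covered"); raw counts are used, since the filter models detectability,
   not composition.

The three filters commute (asserted as a property test), so their order
is a non-issue. On every instance up to 10 kb the whole derivation equals
a per-base source-depth oracle (500 random cases in the acceptance
suite).

## Differential activity

### Normalization

TMM factors are computed exactly in the trimmed, precision-weighted form:
against a reference column (the sample whose upper-quartile count
fraction is closest to the mean — the standard convention when no
reference is named), per-region `M = log2((y_j/N_j)/(y_r/N_r))` and
`A = ½·log2((y_j/N_j)(y_r/N_r))` are formed over finite entries, the top
and bottom 30% of M and 5% of A are discarded, and the factor is `2^` the
mean of the surviving M values weighted by inverse delta-method variances
`(N−y)/(N·y)` summed over the two samples. Factors are rescaled to
geometric mean 1 (enforced to 1e−9 in tests). The implementation is
cross-checked against an independent reference implementation (edgeR's
`calcNormFactors`) to 1e−10 on random matrices; that package is never
used as the computation path.

### Replicate grouping

Samples arriving without declared replicates are merged, in column order
within their mark, into the existing group whose mean log-scale
normalized profile they best correlate with — provided Pearson
*r* exceeds 0.89 — and otherwise start a singleton group. The greedy,
order-deterministic rule makes grouping reproducible; the threshold is a
tunable with the conventional default.

### Model, dispersion, and test

Counts are modelled as negative binomial, `Var(y) = μ + φμ²`, with log
link and per-sample offsets `log(N_j·f_j)` (effective library sizes). One
common dispersion φ is estimated per mark × factor analysis by
maximizing the Cox–Reid adjusted profile likelihood — the NB
log-likelihood at the per-region fit minus half the log-determinant of
the Fisher information — over a log10 grid from 1e−6 to 10 refined by
golden-section search, clipped to `[1e−8, 10]`. A flat profile up to the
lower grid edge is reported as effectively Poisson (φ = 1e−8). No
trended or tagwise shrinkage is attempted: region-level variability is
carried by the quasi-likelihood layer instead, which keeps the model
tractable while preserving error control; numerical identity with any
particular implementation of the same framework is not claimed.

The package's designs are one-way layouts (intercept plus one factor:
developmental time point or brain region), so fitting reduces to
group-wise scalar Newton iterations on the score equation
`Σ (y−μ)/(1+φμ) = 0`, vectorized across all regions (steps clamped to
±5, convergence at 1e−10, 60 iterations). A general IRLS fitter
(`fitNbGlm`, convergence `max |Δβ| < 1e−8`, 50 iterations) implements
arbitrary full-rank designs; the two are cross-checked on shared
instances, and non-converged fits are flagged and conservatively assigned
p = 1 so that numerical trouble can never create a spurious DAE.

The quasi-likelihood F-test divides the per-region deviance difference
per test degree of freedom by a moderated quasi-dispersion. The
quasi-dispersions `s²_g = deviance_g/df` are shrunk toward a common value
with `priorDf` pseudo-degrees of freedom. **Design choice:** `priorDf`
defaults to `"auto"` — the prior degrees of freedom and prior value are
estimated by moment-matching the scaled-F distribution of the `s²_g`
(log-scale mean and variance against digamma/trigamma moments, trigamma
inverted by Newton iteration). A fixed small prior (e.g. 10) discards
most of the information that the residual variation is homogeneous: on
matched simulations it leaves the pooled caller with roughly half the
sensitivity of the empirical prior at identical false discovery control,
and the empirical estimate agrees closely with the established
quasi-likelihood implementations. A numeric `priorDf` remains available,
and `priorDf → ∞` recovers the pooled-denominator F exactly (asserted in
tests).

P values are BH-adjusted *within* each mark × factor analysis — each
analysis is its own multiple-testing family, matching how per-matrix
differential testing is done in practice. A region is a DAE iff its FDR
falls below α = 0.05 in at least `minAnalyses = 2` distinct analyses.
Pooling by intersection is conservative under independence; on pure-null
synthetic data the DAE rate is far below α (asserted), and under the
default generator the pooled caller's empirical false discovery
proportion averaged over ten seeds is reported by
`scripts/acceptance.R`.

## Gene linking

A link requires: a pCR overlapping one 10 kb anchor of a significant
interaction, a gene TSS inside the partner anchor, both inside a single
TAD of the interaction's context (CP or GZ), and gene biotype
protein-coding or lincRNA. Two choices were genuinely open:

- genes meet anchors via their **TSS** (a single base), not their body —
  loop calls are promoter-anchored, and body overlap would link genes
  whose promoter is elsewhere;
- TAD membership uses the **pCR midpoint** and the TSS, which avoids
  double-membership of boundary-straddling regions and is deterministic.

Group comparisons of linked-gene expression use the two-sample rank-sum
(Mann–Whitney) test: the compared groups (e.g. genes linked to DAEs vs
others) are independent samples, so the paired signed-rank construction
does not apply; the exact null distribution is enumerated when both
groups have ≤ 8 tie-free observations, and the normal approximation with
tie and continuity corrections is used otherwise. Trajectory-class odds
ratios (falling/rising/constant) reuse the contingency machinery below.

## Rescaled-bin metaprofiles

Regions of 50–1000 bp are cut into 10 bp bins from the region start (the
last bin may be short). Bin `i` of `B` maps to relative position
`1 + round((i−1)·99/(B−1))`, rounding half away from zero so the mapping
is symmetric in both halves of the region; the first bin is always
position 1, the last always 100, and a single-bin region maps to the
center (50). Per bin, score tracks contribute the median of base-level
values and read tracks a log2 count; when several bins of one region
collide on one relative position they are averaged *before* regions are
combined, so long regions cannot dominate a position. The central subset
spans the bins with positions in [40, 60]; a region too short for any bin
to reach that window contributes its middle bin. Mean region scores are
base-weighted with uncovered bases excluded from the denominator, and a
fully uncovered region is missing, not zero.

## Contingency statistics

The two-sided Fisher exact p sums, in log space via `dhyper`, the
probabilities of all tables (margins fixed) no more likely than the
observed one, with the same 1e−7 relative slack as R's `fisher.test` —
that rule is what makes published `fisher.test` p values the comparison
standard. The reported odds ratio is the *sample* cross-product ratio
`(a·d)/(b·c)`, not the conditional MLE, because that is the quantity
published alongside such tables. The Haldane–Anscombe correction (+0.5 to
every cell) is applied **only when a zero cell exists** (`"auto"`): an
unconditional correction would visibly shift tables that need none. The
95% CI is the log-OR normal approximation on the possibly corrected
cells. Transposable-element enrichment uses relative frequency
`f_all = n_overlaps/n` in the pCR universe, expectation
`E = f_all · n_test`, observed `O` counted once per region per family,
with families at `n_overlaps ≤ 15` excluded as too rare to interpret, and
calls enriched above `O/E = 1` and depleted below `0.5`.

## Temporal clustering

Rows (DAEs) are log2-scaled normalized counts; the distance is
`1 − ρ` with Spearman's ρ (average ranks for ties), so monotone
trajectory shape, not amplitude, drives the grouping. Constant rows have
undefined rank correlation; their distance is defined as 1 to all
non-identical rows and flagged with a warning. k-medoids is used rather
than k-means for robustness to outliers; instances with ≤ 10 rows are
solved exactly by enumerating medoid subsets (the BUILD+SWAP heuristic
can stop in a local optimum precisely on such tiny inputs, where
exhaustive search is free), larger instances use BUILD+SWAP from the
`cluster` package, and ties break toward the lexicographically smallest
medoid set. A hierarchical-linkage parameter (ward.D2) cannot
parameterize a k-medoids procedure and is not emulated. The number of
clusters is chosen by bootstrap: each resample votes for the k in 2–6
maximizing mean silhouette width, the majority wins, and ties go to the
smaller k. The default of 100 resamples keeps desk-scale runtime; results
are stable against raising it. Silhouette widths follow the usual
`(b−a)/max(a,b)` with singleton clusters assigned 0.

## What the generator emulates — and what it does not

The synthetic generator produces every input the pipeline consumes, each
from its own RNG stream derived from the master seed by a stable label
(adding an output never perturbs the others; identical configurations are
byte-identical on disk).

- **Enhancer catalogs**: planted true enhancers (150–800 bp) reported by
  a random subset of `nSources = 4` sources with Normal boundary jitter
  (`jitterSd = 20` bp, clipped at 50 bp length), a
  `fracMultiSource = 0.8` multi-source fraction, and injected exact
  duplicates to exercise deduplication.
- **Counts**: `y ~ NB(depth·libFactor·rel_g·FC, φ)` with lognormal
  region effects, library factors uniform in `[0.5, 2]`, `depth = 50`,
  `φ = 0.05`, and 10% of regions carrying a planted trajectory. The
  planted log2 fold change (magnitude uniform in `[1, 2]`, random sign,
  identical in every mark so the pooled caller can find it twice)
  applies to **every stage transition**: `FC(t) = 2^(lfc·(t−1))`. This is
  the reading under which the stated conditions are self-consistent —
  each adjacent-stage change has |log2 FC| ≥ 1 — and it mirrors
  progressive developmental activation; a region whose *total* span
  across all stages were only 2-fold would sit at the detection boundary
  of any NB-GLM caller at this depth and replication.
- **Linking layer**: TADs tile the chromosome at 400 kb, loops connect
  the 10 kb bin of an enhancer midpoint to a TSS bin, intra-TAD with
  probability 0.8; genes linked to differential enhancers get 2.5× fetal
  expression.
- **Tracks, repeats, variants**: score tracks are a flat background with
  a Gaussian bump (sd = length/6) at region centers sampled at 10 bp;
  one repeat family is planted at a configurable O/E in the differential
  set (solving `p_dae = r(1−w)p/(1−rw)` so the *ratio*, not just the
  probability, hits the target); case variants hit differential regions
  with the probability whose odds are `targetOR = 2` times the control
  odds (`baselineHitRate = 0.2`), and non-hitting variants are placed in
  guaranteed inter-region gaps.

The generator does **not** model read-level noise (fragment sizes,
mappability, GC bias), chromosome-scale heterogeneity, correlated calls
between sources, trended mean–dispersion relationships, or anything
about real TAD nesting. Passing tests therefore demonstrate algorithmic
correctness and calibrated error control under the declared model — not
performance on real epigenome data, where trended dispersion and
batch structure can matter.

## Problem sizes and numerical conventions

The test and acceptance workloads use 5,000 regions × 12 samples for
error-control measurements (ten seeds), 2,000–4,000 regions for
enrichment calibrations (fifty seeds), exhaustive enumeration for all
2×2 tables with grand total ≤ 60, and 500 random instances for the pCR
oracle — sizes chosen so the whole suite runs comfortably on one CPU
while keeping Monte-Carlo noise well below the asserted margins.
Remaining conventions: deviance uses the NB form with the `y log(y/μ)`
term zero at `y = 0` and the Poisson limit below φ = 1e−10; all
simulations take explicit seeds and no hidden global state; library
sizes are observed column sums.

## Known limitations

- The common-dispersion-plus-QL layer does not model a mean–dispersion
  trend; strongly trended real data would deserve one.
- Replicate grouping is greedy and order-dependent by design
  (deterministic), not a global optimum over partitions.
- Gene linking treats anchors as given; no attempt is made to re-call or
  re-weight interactions (activity-by-contact style scoring is out of
  scope).
- GC content can be computed from a FASTA (`gcTrack()`) or consumed as a
  precomputed track; the two paths are asserted to agree on a shared
  fixture, but no other sequence-derived feature is computed in-package.
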