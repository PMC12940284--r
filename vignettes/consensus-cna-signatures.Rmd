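---
title: "Consensus copy-number signatures from targeted panels: methods"
author: "cnasig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus copy-number signatures from targeted panels: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnasig)
```

## The problem

Clinical targeted panels (a few hundred cancer genes, under 2% of the
genome) produce sparse somatic copy-number alteration (CNA) profiles:
segments with a log2 copy ratio or an integer total copy number, usually
without allele-specific calls. `cnasig` implements a complete framework for
this setting: encode segments into a compact feature space, extract
candidate signatures with several deconvolution algorithms, merge them into
validated consensus signatures, and refit those signatures into new samples
with per-sample quality control.

Because no single matrix-factorization algorithm is uniformly reliable on
sparse panel data, the central idea is *consensus across algorithms*:
patterns that several unrelated deconvolution methods discover
independently are more trustworthy than the output of any one of them.

## The 28-category feature space

Each segment is classified by total copy-number state and length:

* homozygous deletion (0 copies): lengths 0–100 Kb, 100 Kb–1 Mb, ≥ 1 Mb;
* LOH (1 copy), diploid (2), gain 3–4, gain 5–8, gain 9+: lengths
  0–100 Kb, 100 Kb–1 Mb, 1–10 Mb, 10–40 Mb, ≥ 40 Mb.

That is 3 + 5 × 5 = 28 mutually exclusive, jointly exhaustive categories.
Length intervals are half-open `[lo, hi)`; a segment of exactly 100 Kb
falls in the upper class. This resolves boundary ties deterministically.
With only total copy number available, 1 copy is the operational proxy for
LOH; copy-neutral LOH cannot be represented and is a known blind spot of
panel releases.

A sample's feature vector records, per category, the fraction of its
*segmented* genome (not the whole genome) in that category, so every
non-empty row sums to 1 and the encoding is invariant to uniform rescaling
of segment lengths. Using the segmented length as denominator is the
natural choice for panels, where the covered footprint varies by design;
it also yields a testable conservation invariant.

Log2 ratios convert to integer copies as `round(ploidy * 2^ratio)` with
half-away-from-zero rounding, floored at 0. Purity correction is out of
scope; ratios are taken at face value.

## Extraction backends

All four backends return non-negative, L1-normalized signature profiles
with method provenance, and are deterministic given a seed.

**NMF.** Multiplicative-update NMF under the Frobenius objective. For each
candidate rank, `n_restarts` random initializations are run; restarts are
aligned to the best-objective restart by optimal (Hungarian) assignment on
cosine similarity. Stability is the mean matched cosine; the reported
signatures are per-slot elementwise medians of the matched restarts. The
rank maximizes `stability − min-max-normalized error` with a parsimony band
of 0.01: the smallest rank scoring within the band of the maximum wins,
because adding components for marginal score gains is over-fitting.

**Non-negative ICA.** NMF initialization followed by alternating symmetric
decorrelation (`S ← (S Sᵀ)^{-1/2} S`) and projection onto the non-negative
orthant with L1 renormalization. Decorrelation pushes components toward
orthogonality (a proxy for independence under non-negativity); projection
restores feasibility. Convergence is declared when the largest
per-component change (1 − cosine between successive iterates) drops below
`tol` (default 1e-6, at most 500 iterations); non-convergence returns the
last iterate flagged, not an error. The independence diagnostic is the
mean absolute pairwise correlation of the refit activities.

**Graph-regularized NMF (GD).** A graph over the 28 categories is built
from the absolute Pearson correlations between category columns (self-loops
removed, weights under 0.1 pruned — a sparsity choice, since near-zero
correlations are noise at cohort scale). With `L = D − W` the combinatorial
Laplacian, the objective adds `alpha_graph·tr(S L Sᵀ)` (correlated
categories should carry similar loadings), a pairwise-cosine diversity
penalty (discourages redundant signatures), and an L1 sparsity penalty.
Updates remain multiplicative, with penalty gradients split into
positive/negative parts. Because the factorization scale is ambiguous,
the columns of the activity factor are pinned to unit norm whenever a
penalty is active, so penalty weights act on a fixed scale; with all
penalties zero the code path is exactly plain NMF. Defaults
(`alpha_graph = 0.02`, `beta_diversity = 0.01`, `gamma_sparsity = 0.005`)
are deliberately gentle: regularization should shape, not dominate, the
fit at typical cohort sizes.

**HDP.** Feature rows are discretized to pseudo-counts
(`round(count_scale · x)`, default 1000 per sample) and modeled with a
collapsed Gibbs sampler over a weak-limit (truncated) hierarchical
Dirichlet process mixture: tokens from every sample share a pool of at
most `k_max` components with a symmetric Dirichlet base over the 28
categories, and a small per-component concentration lets unused components
empty out — the number of signatures is inferred, not fixed. Components
holding over 1% of tokens in more than 5% of post-burn-in sweeps are
reported as posterior-mean category distributions. The truncation can keep
several interchangeable copies of one component alive (their profiles are
finite-count estimates of the same distribution), so reported components
agreeing at cosine ≥ 0.9 are merged before output. This is a desk-scale
approximation to full Chinese-restaurant-franchise samplers; truncation
level and concentrations are exposed, and the sampler core is compiled
(Rcpp) for throughput.

## Consensus merging

Signatures pooled across backends are compared by pairwise cosine
similarity (scale-invariant, appropriate for compositional profiles) and
clustered hierarchically with Ward linkage on the dissimilarity
`1 − cosine` — used as-is, without a metricity correction; this is the
standard pragmatic pairing even though `1 − cosine` is not a metric.

A cluster is *valid* if it satisfies at least one of: members span ≥ 2
methods; the cluster holds ≥ 26% of the signatures one method contributed
to the pool; or ≥ 3 members come from a single method. The 26% rule is
interpreted per contributing method (a "substantial share of at least one
method's output"), and the satisfied criterion is logged per cluster so
users can audit the decision. The cluster number is chosen from a
configurable range (default 4–15) to maximize the fraction of valid
clusters, ties toward fewer clusters.

Consensus profiles are unweighted elementwise medians of the member
signatures (robust to outlier signatures, no distributional assumptions),
L1-renormalized, and labeled `CON1..CONm` ordered by descending total
pooled exposure share (cluster size when exposures are absent; the
numbering is presentational only). Diagnostics report mean silhouette
width, cophenetic correlation, mean distinct methods per cluster, and the
NNLS reconstruction error of the cohort against the consensus signatures.

Stability is assessed by subsampling (default 100 iterations at 80%,
without replacement — subsampling, not a with-replacement bootstrap),
rerunning extraction and consensus, and matching resampled consensus
signatures to the originals by optimal assignment on cosine; the report
gives the per-signature mean Pearson correlation of matched pairs.
Optimal assignment (rather than greedy best-match) makes the matching
deterministic and order-free. The default stability protocol excludes the
HDP backend from the resampled reruns: its inferred component count varies
most under subsampling, and the remaining three backends already span the
cross-method validation criterion; this keeps the resampling loop
affordable at 100 iterations.

## Fitting new samples

Given fixed signatures, per-sample activities solve
`argmin_{a ≥ 0} ||x − aᵀS||² + l2·||a||²` via Lawson–Hanson active sets on
the ridge-augmented design. The default ridge `l2 = 1e-6` only guards
against near-collinear signature sets; activities are reported in
feature-fraction units (`log2(a + 1)` is available for display). A
non-negative elastic net (`glmnet`, no intercept, no standardization) is
provided as the documented alternative; at zero penalty it coincides with
unregularized NNLS.

Quality control per sample: Pearson correlation `r` between observed and
reconstructed feature vectors, `R²` against the observed vector's mean
(the standard definition), RMSE, and the high-quality flag `r > 0.8`. The
cohort summary reports both the mean per-sample correlation and the
correlation of stacked observed/reconstructed values, since the two
conventions differ and both are in circulation.

## Downstream correlates

`compute_fga` follows the cBioPortal convention: the length-weighted
fraction of the segmented genome with `|log2 ratio| ≥ 0.2` (or integer
copies ≠ 2); empty samples are missing, not zero. Activity–alteration
associations use two-sided Mann–Whitney tests with Cohen's d on the pooled
standard deviation (the field default when no convention is stated;
recorded in output metadata), gene filters at ≥ 1% alteration frequency,
and BH false-discovery control per scan; effects with `|d| > 0.2` are
flagged. Enrichment compares each signature's high-activity samples (top
50% by default, exposed as a quantile) against samples high in at least
one other signature via Fisher's exact test, reporting the sample odds
ratio, a Haldane-corrected estimate when a margin is zero, and fold
enrichment with the `> 1.2` flag. Median splits send ties to "low" —
deterministic and documented. Early-progression odds ratios reuse the same
machinery with BH adjustment within the declared test family.

## The synthetic cohort generator

The generator is the package's test bed and defines its study conditions.
It emulates: sparse Dirichlet signatures with pairwise cosine ≤ 0.6
(rejection-sampled); one diploid-like signature carrying ≥ 90% of its mass
on 2-copy categories, active in every sample — the near-diploid background
state that dominates panel cohorts; activation prevalences spanning
ubiquitous (1.0) down to rare (0.25); gamma-drawn, row-normalized
exposures; multiplicative lognormal noise with log-sd equal to
`noise_level` (a Dirichlet resampling model is available); and a
segment-level realization that places class-consistent, non-overlapping
segments on an hg19-scale genome so the SEG reader and classifier are
exercised end to end. By default no mass is placed on homozygous-deletion
or 9+ categories, mirroring their near-absence in public panel releases.

It does *not* emulate: breakpoint hotspots, chromosome-arm structure,
purity or subclonality, panel-specific coverage bias, or correlated noise
between categories. Passing tests therefore demonstrate algorithmic
correctness under controlled conditions, not performance on any real
cohort.

Numerical details of the realization: per-category target lengths are
drawn log-uniform within the class interval and rescaled to the exact
target (equal lengths as a fallback); fractions smaller than half the
class minimum divided by the per-sample segmented length (default 2 Gb)
are unrealizable and dropped, fractions between half and one class minimum
snap up to a single minimal segment — both effects are bounded well below
the 0.02 round-trip tolerance the tests enforce. Segments are placed
first-fit-decreasing with 10 Kb gaps.

## Problem sizes and reproducibility

The test suite and the acceptance script work at desk scale, chosen so a
single CPU covers them comfortably while still exercising every code path:
study-scale cohorts of 300 samples with 4 planted signatures at 5%
noise, 20-sample cohorts for segment-level round trips, 20 subsampling
iterations for the stability check (the API default remains 100), and
50 random instances for the NNLS-versus-grid oracle. All randomness flows
from explicit seeds; identical seeds reproduce cohorts, factorizations and
reports bit-for-bit.

## Known limitations

* LOH is approximated by total copy number 1; allele-specific signal is
  not represented.
* The HDP backend is a truncated approximation; its inferred component
  count is the least stable of the four backends under resampling.
* Ward linkage on `1 − cosine` is a pragmatic, not theoretically clean,
  choice.
* Signature fractions depend on the panel footprint; signatures derived on
  one panel design do not automatically transfer to another.
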