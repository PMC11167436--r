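---
title: "Methods: integrative histology-to-metabolism modeling for EED"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative histology-to-metabolism modeling for EED}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the models and procedures
it implements, the parameters that matter, the numerical choices made
where the design was genuinely open, and what the synthetic-data tests
do and do not demonstrate.

## The pipeline in one paragraph

Duodenal biopsy whole-slide images are tiled into patches and classified
disease/control by a convolutional network; the pre-final-layer
activations of each patch form a morphological fingerprint, which is
aggregated per patient with the predicted disease probability as weight.
Those patient representations are screened against gene expression,
clinical biomarkers and binary enteropathogen markers. In parallel, each
subject's transcriptome contextualizes a genome-scale metabolic network
— pruning transcriptionally unsupported reactions under a parsimony
objective while preserving the biomass optimum — and sampled steady-state
fluxes feed a repeated random-forest procedure that extracts the
reactions separating the groups. Finally, lipidomic intensity tables are
tested for class-level enrichment along the fold-change ranking.

## Histology

**Patch bookkeeping.** Tiles form a regular non-overlapping grid anchored
at the slide's top-left corner, with 0-based half-open tiles
`[r, r+P) x [c, c+P)`; incomplete border tiles are dropped rather than
padded (padding would manufacture blank-glass context the scanner never
produced). A patch is kept when at least half its pixels are tissue. A
pixel counts as tissue when its HSV saturation exceeds 0.08 **or** its
brightness falls below 0.85: stained material is either colorful (eosin)
or dark (hematoxylin nuclei), while blank glass is bright and gray. Both
thresholds are exposed in `tissue_fraction()`.

**Stain normalization** follows the stain-matrix factorization family:
pixels are mapped to optical density `OD = -log10(I)`, pixels with mean
OD below 0.15 (background) are excluded, the two stain vectors are the
1st/99th-percentile angles of the OD cloud in its top-2 principal plane,
and concentrations are solved by pseudo-inverse and rescaled so their
99th percentiles match the target patch's before recombination with the
target's stain vectors. Each pixel's off-plane OD residual is carried
through unchanged — this is what makes the method structure-preserving
and makes normalizing a patch to itself an exact identity. A constant
target is an error; a stain-free source is returned unchanged with a
warning.

**The classifier.** The reference architecture in this literature is an
18-layer residual network whose 512-wide pre-final layer supplies the
feature fingerprint. This package implements a compact convolutional
network with the same interface contract — softmax class probabilities,
a nonnegative global-average-pooled pre-final feature vector (width `F`,
default 16–32), saliency from the last convolutional block — at a size a
CPU trains in under a minute: two conv/ReLU/maxpool blocks, a final
conv/ReLU block, global average pooling and a dense softmax head,
trained by minibatch SGD with momentum 0.9 and a step-decayed learning
rate (1×/0.3×/0.1× at 60% and 85% of the epochs; the late decay settles
the oscillation that a constant rate shows on these small cohorts).
Training and validation are always split at the **subject** level,
stratified by class, 80/20; every patch inherits its subject's label
(control subjects are assumed lesion-free everywhere). The split,
initialization and data order are functions of the seed; exact bitwise
reproducibility across BLAS builds is not promised, so tests assert
split determinism and accuracy bands rather than weight equality.

**Saliency.** Because the classifier head acts on a global average pool,
the gradient-weighted class-activation map has closed-form channel
weights — the head's weights for the target class divided by the spatial
area — so the map is the rectified weighted channel sum, min-max
normalized and bilinearly upsampled. The last convolutional block is the
conventional (and here the only meaningful) target layer. Localization
is scored by whether the saliency center of mass falls within the
planted lesion mask dilated by 10% of the patch side.

## Patient aggregation and screens

Patches aggregate to a slide by probability weighting
(`Σ pᵢ fᵢ / Σ pᵢ`, a convex combination, order- and scale-invariant) and
slides to the patient by unweighted mean; the second step is a package
choice since only the first is specified by the aggregation convention
we follow. If all probabilities are zero — conceivable for a control
subject under a confident model — the fallback is the unweighted mean,
with a warning.

The gene screen computes Pearson r for every gene × feature pair with
the t-transform p-value (n − 2 df), and Benjamini–Hochberg q-values over
the **single family of all pairs** (not per feature), since one q
threshold is applied to the whole screen. Pairs are kept at `r > 0.7`
and `q < 0.05`, both strict. The biomarker screen reports raw `p < 0.01`
with pairwise deletion of missing values and per-test n (clinical panels
have variable availability); an optional BH flag is available but off by
default because the screen is defined on raw p. Binary TAC markers use
the two-sided Mann–Whitney U (U counts positive-subject > negative-subject
pairs), exact by enumeration when `min(n₁,n₂) ≤ 8` and `n₁+n₂ ≤ 25`,
tie-corrected normal with continuity correction otherwise.

## Metabolic contextualization

Networks carry stoichiometry, bounds, GPR boolean rules, subsystems and
one objective; exchange reactions touch exactly one metabolite with the
usual sign convention (negative lower bound = uptake). Infinite bounds
are capped at ±1000. FBA is a plain LP; the primary solver is
`boot::simplex`, with a package-internal two-phase simplex (Bland's
rule) as automatic fallback for the rare degenerate pivots the primary
aborts on. Feasibility tolerance is 1e-6 and the blocked-reaction
tolerance 1e-9 throughout, so tests can be exact.

Contextualization proceeds in four steps per subject:

1. genes absent from the measured set are deleted from GPR trees (an
   unmeasured isozyme drops out of an OR; an unmeasured complex subunit
   kills its AND);
2. abundances map to reactions by AND→min / OR→max (the standard
   enzyme-complex/isozyme convention; swappable), with gene-free
   reactions taking the median of the gene-bearing ones;
3. weights `wᵣ = 1 − aᵣ/max(a)` (max-scaled per subject; zero-TPM genes
   are valid abundances and yield weight 1) plus a uniform tie-break of
   1e-3 enter a weighted parsimonious LP — minimize `Σ wᵣ|vᵣ|`,
   linearized by flux splitting, subject to steady state, bounds, and
   objective ≥ `objective_fraction` × optimum (default 1.0). The
   tie-break makes the objective strictly positive, so uniform
   abundances reduce exactly to plain parsimonious-FBA support;
4. flux variability under the budget `Σ wᵣ|vᵣ| ≤ min + 1e-9` decides
   pruning: a reaction whose range stays within `10 × slack / wᵣ` of
   zero is slack-noise and is removed (the per-reaction radius is what
   keeps a 1e-9 budget slack from shielding reactions behind small
   weights). Retained internal reactions then receive contextualized
   bounds — their flux range when the budget is relaxed by
   `budget_relax` (default 1%) — so each subject's permissible flux
   ranges reflect the transcript evidence; exchange bounds are never
   edited (no medium changes).

The pruned model's optimum is verified to stay within 1e-6 of
`objective_fraction` × the parent optimum.

**Flux sampling** uses artificial-centering hit-and-run in the null
space of S (an orthonormal SVD basis, so `S v = 0` holds to machine
precision by construction), warm-started from flux-variability vertices,
with 100 warm-up steps and thinning 10 (exposed parameters; the default
of 50–500 samples matches the conventional range, and values outside it
warn). A zero-volume polytope returns the unique solution replicated,
with a warning.

## Discriminative reactions

Per-subject sample matrices are joined on the **intersection** of their
reaction sets. A reaction is excluded as "similar flow" when it is
constant over all samples, when the two groups' pooled values are
identical as multisets, or when the two-sided Mann–Whitney p is ≥ 0.99
(near-total overlap); the policy and threshold are logged and
configurable, since "similar" is not otherwise defined. The classifier
is a 100-tree random forest with sqrt-features per node and impurity
importance; 100 stratified 80/20 row splits are run, test rows never
overlapping training rows within a split, and the top-10 reactions by
importance are recorded per split. Aggregation counts selections over
the splits with accuracy strictly above 0.60, breaking ties by median
importance rank then reaction id. Row-level splitting follows the
flux-point-independence convention, but because all samples of a subject
share that subject's contextualized bounds, row splits leak subject
identity: a forest can recognize *which subject* a test row comes from
even with no group signal. The permuted-label null (shuffling row labels)
is therefore the correct chance control, and `split_by = "subject"` is
provided for leakage-free evaluation. The group comparison for reported
reactions is the two-sided Mann–Whitney test at 0.05 (one primary-source
statement of "p < 0.5" is treated as a typo for 0.05; the threshold is
an argument).

## Lipidomics

Species names are parsed by the grammar `CLASS(C:D)` / `CLASS C:D` with
`O-`/`P-` ether prefixes; anything else becomes class "unknown" with a
warning rather than an error, because real annotation exports always
contain stragglers. Intensities are `log2(x + 1)` (pseudocount 1,
configurable — standard for zero-inflated intensity tables) and
median-centered per sample. Fold changes are disease − control means on
the log scale with a two-sided Welch t p-value (the package does not
moderate variances; at the tested group sizes moderation changes little
and plain Welch keeps the oracle simple). Enrichment uses the GSEA-style
weighted Kolmogorov–Smirnov running sum with weight `|logFC|¹` and a
species-label permutation null:
`p = (1 + #{|ES_null| ≥ |ES|})/(B + 1)` — never below `1/(B+1)` — and
the normalized score is `ES / mean|ES_null|`. Classes with fewer than 3
present members are skipped; a class covering the whole list has no
complement and is an error. PCA treats samples as observations with
species mean-centering; explained-variance fractions are the normalized
covariance eigenvalues.

## The synthetic cohort: what it emulates, and what it does not

Slides are stylized: an eosin-pink textured field with darker epithelium
bands, hematoxylin-purple lymphocyte-like blobs, white goblet-like
vacuoles with stained rims, and a blank-glass margin
(`background_fraction` = 0.2) so the tissue filter is exercised. Disease
slides concentrate extra blobs into one infiltration focus per 64-px
lesion cell; the union of focus disks is the ground-truth mask. Defaults
— blob density 30 vs 6 per cell, vacuoles 6 vs 2, crowding 1.6 vs 1.0 —
are the study conditions of this package's experiments: no quantitative
morphological effect sizes are available from primary sources, so they
were chosen once for comfortable recoverability and are not tuned
per test. The generator does not attempt photorealism, scanner
artifacts, magnification variation, or pathology-grade nuclear detail;
passing tests show the pipeline's bookkeeping, learning and localization
contracts hold on recoverable signal, not that the classifier would
reach any particular accuracy on real biopsies.

Expression planting uses the analytic noise calibration
`σ_noise = σ_feature · sqrt(1/r² − 1)`, so the expected sample
correlation equals the target without iteration; per-gene shift-to-zero
and column renormalization (TPM-like, 1e6) leave correlations intact up
to the near-constant column totals. Transcript planting applies the
stated fold change symmetrically (disease × shift, control ÷ shift) so
both groups' route choices are pinned in opposite directions. Lipid
planting multiplies the disease group by `2^logFC` for the planted
classes. Every generator derives independent substreams from one seed
(`substream_seed`), so adding a stream never perturbs the others, and
all outputs are bit-identical for identical calls.

The metabolic test bed is the `coupled_pathways` template: units of two
parallel routes whose capacities (8) are below the unit demand (10), so
*both* routes must run and the transcript weights decide the split. This
is what lets group differences survive into the shared-column flux
dataset: group-specific pruning alone would remove the informative
reactions from the column intersection.

## Problem sizes and runtime

The test and acceptance runs use 6+6 subjects (8+8 for the null cohort)
with 256-px slides and 64-px patches (~12 patches/slide), an 18-epoch
classifier, 50 flux samples per subject on 3-unit networks, 100
random-forest splits, screens of up to 5000 genes × 64 features at
n = 40, and 1000-permutation enrichment — sizes chosen so the full suite
and the acceptance script each run in minutes on one CPU while leaving
all statistical contracts testable at their stated thresholds. The same
code paths scale to the reference settings (512-px patches, 512-wide
features, genome-scale networks) by configuration, with the LP solver
being the first component one would swap for a sparse implementation at
Recon3D scale.

## Known limitations

- The LP stack is dense and sized for toy networks; genome-scale
  reconstructions need a sparse solver behind `solve_lp()`.
- The weighted-parsimony contextualization is one documented
  interpretation of transcript-guided pruning; other published variants
  differ in the weight law and in how sampling interacts with the
  parsimony budget (here: pruning uses the strict budget, bounds a 1%
  relaxed one, sampling only the contextualized bounds plus the
  objective floor).
- Sample-level RF splits leak subject identity by construction (see
  above); subject-level splitting is the honest generalization estimate.
- The stain estimator assumes two dominant stains; it degrades towards
  collinearity when a palette is effectively one-dimensional.
- `n_patches` aggregation treats every slide of a subject equally
  regardless of its patch count.
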