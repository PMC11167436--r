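# eedomics

An R package that re-implements, end to end and at desk scale, an
integrative analysis of **environmental enteric dysfunction (EED)** — a
subclinical small-intestinal enteropathy of children in low-resource
settings. The pipeline links duodenal histology to molecular readouts in
four stages:

1. **Histology features.** Whole-slide images are tiled into
   non-overlapping patches (512 px in the reference setting; incomplete
   border tiles dropped; patches with less than 50% tissue discarded),
   stain-normalized in optical-density space (Macenko-style stain-matrix
   factorization), and classified disease/control by a convolutional
   network. The pre-final layer (global average pool, width *F*) gives a
   nonnegative morphological fingerprint per patch; class-activation
   saliency maps localize the discriminative regions.
2. **Morphology–omics screens.** Patch features are aggregated to the
   patient with the disease probability as weight,
   `v = Σ pᵢ fᵢ / Σ pᵢ`, then screened genome-wide against expression
   (Pearson r with Benjamini–Hochberg q over all gene × feature pairs;
   pairs kept at r > 0.7 and q < 0.05, genes ranked by the number of
   correlated features), against continuous clinical biomarkers
   (p < 0.01), and against binary stool TAC markers (Mann–Whitney U,
   p < 0.05).
3. **Metabolic modeling.** A genome-scale network (SBML L3+FBC or a JSON
   dialect) is contextualized per subject: gene abundances map onto
   reactions through GPR rules (AND→min, OR→max), reaction weights
   `wᵣ = 1 − aᵣ/max(a)` drive a weighted parsimonious FBA holding the
   objective at a configurable fraction (default 1.0) of its optimum,
   blocked reactions are pruned and retained reactions get
   transcript-informed flux bounds. Steady-state fluxes are sampled by
   artificial-centering hit-and-run; a random forest over 100 stratified
   80/20 splits extracts the top-10 discriminative reactions from splits
   with accuracy > 0.60, grouped by metabolic subsystem.
4. **Lipidomics.** Species names are parsed into classes
   (`PC(34:2)`, `LPC(O-18:1)`, …), intensities log-normalized, fold
   changes ranked, and lipid classes scored with a GSEA-style weighted
   Kolmogorov–Smirnov statistic against a species-permutation null,
   alongside PCA with explained-variance fractions.

A first-class **synthetic-data module** generates every input with
planted, machine-readable ground truth (class-discriminative morphology,
gene–feature correlations, differential-flux reactions, lipid-class
shifts), so every stage is testable without any external download.

## Worked example

```r
library(eedomics)
out <- run_pipeline(out_dir = "eedomics_run")   # ~1 minute on one CPU
str(out$report$metabolic[c("planted_reactions", "top_reactions",
                           "median_split_accuracy")])
```

which prints (seed 1, the default configuration):

```
List of 3
 $ planted_reactions    : chr [1:6] "R1_hi" "R1_lo" "R2_hi" "R2_lo" ...
 $ top_reactions        : chr [1:10] "R3_hi" "R3_lo" "R1_hi" "R1_lo" ...
 $ median_split_accuracy: num 0.917
```

All six planted differential reactions appear in the aggregated top-10
and the random forest separates synthetic patients from controls with
median split accuracy 0.92. The same report lists the recovered planted
genes (`out$report$correlation`, all three planted gene–feature pairs
pass r > 0.7 at q < 0.05), the flagged biomarker and TAC associations,
the histology held-out accuracy and saliency localization rate, and the
lipid-class enrichment table with the planted phosphatidylcholine shift
detected as "up". Individual stages are exposed as ordinary functions
(`extract_patches`, `train_classifier`, `gradcam`,
`correlate_gene_features`, `contextualize`, `sample_fluxes`,
`rf_classify_splits`, `lsea`, …); a thin command-line wrapper lives at
`inst/scripts/eedomics.R`.

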