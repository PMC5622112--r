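# morphoscreen

Label-free morphological drug-response profiling from bright-field
single-cell images.

## What it does, and for whom

High-content drug screening normally depends on fluorescent labels.
`morphoscreen` implements the label-free alternative: image thousands of
unlabeled cells in flow with a line-scan bright-field microscope, and let
machine learning detect the drug-induced morphological shift that no
human eye can see in a single cell. It is aimed at image-cytometry and
phenotypic-screening groups who want a tested, reproducible reference
implementation of that analysis.

The pipeline:

1. **Reconstruct** 2-D frames by stacking 1-D line scans
   (`stack_linescans()`), then detect and segment single cells
   (`detect_cell_frames()`, `segment_cell()`).
2. **Extract** a fixed 548-feature morphological profile per cell —
   43 geometry (indices 1–43), 10 granularity (44–53), 43 intensity
   (54–96) and 452 texture (97–548) features (`extract_features()`,
   `feature_registry()`).
3. **Classify** drug-treated vs untreated populations with a linear SVM,
   decision score `Y = w·x + b`, accuracy `A = (X1 + X2)/N` estimated by
   stratified 10-fold cross-validation (`linear_svm()`,
   `cross_validate()`, `dose_response_curve()`, `transfer_matrix()`).
4. **Quantify** the distribution shift without labels using the unbiased
   squared maximum mean discrepancy under a Gaussian kernel,

   MMD² = 1/(m(m−1)) Σ_{i≠j} k(x_i,x_j) + 1/(n(n−1)) Σ_{i≠j} k(y_i,y_j)
   − 2/(mn) Σ_{i,j} k(x_i,y_j),

   per feature space and per feature, with median-heuristic bandwidth,
   MMD-ranked feature elimination and cross-experiment consistency
   (`mmd2_unbiased()`, `per_feature_mmd()`, `elimination_curve()`).

Since no public image set accompanies the method, a first-class
synthetic-data module (`dose_response_model()`, `render_cell_image()`,
`generate_feature_table()`, `simulate_feature_study()`) generates
line-scan streams, cell images and parametric feature tables with a
configurable rise–peak–rollback dose response (negative control plus a
1 nM–10 µM dilution series, 12 h and 24 h durations, two experimental
repeats). See the methods vignette
(`vignettes/morphoscreen-methods.Rmd`) for the models, parameters and
design decisions.

## Worked example

```r
library(morphoscreen)

model <- dose_response_model()        # EC50 50 nM, peak 1 uM, rollback 30%
cfg <- run_config(model = model, n_per_condition = 1000, seed = 42)
report <- run_pipeline(cfg)
print(report)
```

```
Pipeline run report
  path: table, n/condition: 1000, seed: 42
  per-dose accuracy (24 h):
       1e-09 M: A = 0.505 +/- 0.006
       1e-08 M: A = 0.522 +/- 0.004
       1e-07 M: A = 0.719 +/- 0.002
       1e-06 M: A = 0.822 +/- 0.005
       1e-05 M: A = 0.728 +/- 0.004
  whole-space MMD argmax dose: 1e-06, 1e-06
  elimination: accuracy 0.823 with all 548 features, 0.613 with 1
```

Reading the output: accuracy is at chance (≈0.5) at 1 nM, climbs with
dose, peaks at 1 µM and rolls back at 10 µM — and the unsupervised
whole-space MMD identifies the same peak dose in both simulated
experimental repeats, confirming that the supervised and unsupervised
readouts agree on where the morphological shift is largest. The report
also carries per-class score histograms, the per-feature MMD ranking for
each repeat, the feature-elimination curve (peaking at 0.901 with 55 of
548 features at this sample size) and the cross-condition transfer
matrix.

Single-cell images work the same way end to end:

```r
cell <- render_cell_image(phenotype_params(), acquisition_params(), seed = 7)
fv <- extract_features(cell)   # named vector of 548 finite features
```

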