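---
title: "Label-free morphological drug-response profiling: models and methods"
author: "morphoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free morphological drug-response profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoscreen)
```

## The problem

High-content drug screening usually relies on fluorescent labels, which
are costly, can perturb the biology, and are unavailable for many
targets. An alternative is to image unlabeled cells in flow at very high
throughput with line-scan bright-field microscopy and let statistics find
the morphological changes that a drug induces — changes that are
individually too subtle to see, but detectable in populations of
thousands of cells.

`morphoscreen` implements that analysis end to end:

1. **Reconstruction** — a line-scan camera emits one 1-D intensity trace
   per laser pulse; stacking consecutive lines rebuilds 2-D frames
   (`stack_linescans()`), from which single cells are detected and
   segmented (`segment_cell()`).
2. **Feature extraction** — each cell becomes a fixed, registry-ordered
   vector of 548 morphological descriptors (`extract_features()`).
3. **Supervised discrimination** — a linear support-vector machine
   separates drug-treated from untreated populations; its
   cross-validated accuracy is the dose-response readout.
4. **Unsupervised divergence** — the unbiased squared maximum mean
   discrepancy (MMD) quantifies the distribution shift without labels,
   ranks features by their individual shift, and drives feature
   elimination.

Because no public single-cell image set accompanies the method, the
package ships a synthetic-data module that generates line-scan streams,
cell images, and fast parametric feature tables with a configurable
dose-response structure. All validation runs on that generator.

## The dose-response generator

`dose_response_model()` maps concentration and treatment duration to a
normalized effect size in $[0, 1]$ with a Hill curve
$h(c) = c^k / (c^k + \mathrm{EC}_{50}^k)$, reduced by a fixed
`rollback_fraction` above `peak_dose` and scaled by `duration_scale`
for the shorter treatment. Defaults (chosen once, as the study design
the package emulates):

| parameter | default | meaning |
|---|---|---|
| `doses` | 0, 1 nM … 10 µM | negative control + 10-fold dilution series |
| `ec50` | 50 nM | Hill midpoint |
| `hill_k` | 1 | Hill slope |
| `peak_dose` | 1 µM | maximal effect; accuracy and MMD peak here |
| `rollback_fraction` | 0.3 | effect loss at 10 µM (e.g. solvent toxicity) |
| `duration_scale` | 0.6 | 12 h effect relative to 24 h |

The rise–peak–rollback shape and the 12 h < 24 h ordering are the two
qualitative facts every downstream analysis must recover; tests assert
both.

Two generator paths share this effect model:

* the **image path**: `sample_phenotype()` shifts per-cell phenotype
  parameters (radius, eccentricity, texture grain, interior intensity,
  edge blur) by `effect × displacement` plus truncated-normal
  cell-to-cell variation, and `render_cell_image()` draws the cell — an
  area-preserving ellipse with Gaussian-filtered white-noise texture
  (filter sigma = `texture_grain`, so granularity and Haralick features
  respond monotonically), a logistic edge whose 10–90% transition width
  is `edge_sharpness` pixels, and additive Gaussian acquisition noise;
* the **table path**: `generate_feature_table()` draws 548 independent
  unit-variance normal features whose class mean is shifted by
  `effect × shift`. The default `shift` moves 32 features across all
  four categories by 0.5 sd each, a full-effect separation
  $\lVert\delta\rVert = 0.5\sqrt{32} \approx 2.83$, for which the
  Bayes-optimal linear rule attains $\Phi(2.83/2) \approx 92\%$ —
  the separability regime the method is designed to operate in.

What the generator deliberately does *not* model: optical physics of the
time-stretch acquisition (dispersion, spectral encoding), multi-cell
frames/doublets, fluorescence, feature-feature correlation in the table
path, and batch drift between experimental repeats (available via
`batch_sd`, but off by default so that zero-effect conditions are exactly
exchangeable). Passing tests therefore demonstrate the *pipeline's*
correctness and calibration, not biological fidelity to any particular
cell line or compound; the displacement directions are a free design
choice, not a claim about real drug responses.

All generators are pure functions of their parameters and a seed; RNG
state is saved and restored around every call.

## Reconstruction and segmentation

Serialization and stacking are exact inverses, and the tests assert the
bit-exact round trip. Segmentation is the minimal standard chain:
per-frame min–max normalization, a light Gaussian smooth (sigma 0.8 px)
to stop interior texture from rippling the threshold contour, a global
Otsu threshold refined by IsoData (Ridler–Calvard) iteration — plain
Otsu lands off the half-rise point of a blurred edge when the background
mode dominates — then morphological closing (disc, radius 2),
hole-filling, largest connected component, and a minimum-area filter
(50 px). Frames with several surviving components keep only the largest,
matching the dilute-flow assumption of at most one cell per frame. The
cell is cropped to a fixed 64 × 64 window centred on the mask centroid
(fixed size keeps the feature extractor simple; whether the original
study cropped fixed windows or tight boxes is unknown, and this choice
is flagged as such). On generator output, ground-truth
intersection-over-union is ≥ 0.95 at the default noise level.

## The 548-feature registry

The method's feature space is fixed by category counts and index ranges:
43 geometry (1–43), 10 granularity (44–53), 43 intensity (54–96) and
452 texture (97–548) features. The identities inside each category are
not published anywhere, so the package defines a versioned registry with
standard compositions and asserts the counts at test time:

* **geometry** — 13 shape scalars (area; corner-corrected chain-code
  perimeter with Vossepoel–Smeulders weights 0.980/1.406, accurate to
  ~1% on digital disks; form factor $4\pi A/P^2$; solidity; extent;
  eccentricity, axis lengths and orientation from second central moments
  with the 1/12 pixel-extent correction; compactness; equivalent
  diameter; max/min Feret by rotating calipers) + 30 Zernike moment
  magnitudes (orders 0–9, non-negative repetitions of equal parity),
  computed on the binary mask mapped to its enclosing circle;
* **granularity** — a 10-scale granular spectrum: the fraction of masked
  intensity removed between morphological openings with disc radii
  $s-1$ and $s$, $s = 1..10$; non-negative, summing to at most 1;
* **intensity** — 10 statistics of the masked intensities, the same 10
  on the 1-px boundary ring, mass displacement, intensity-weighted
  centroid, and mean/CV in 10 concentric equal-area rings;
* **texture** — 13 Haralick statistics of the symmetric, normalized
  gray-level co-occurrence matrix (8 levels quantized over the masked
  range, ties to the lower bin, both pair ends inside the mask) at
  4 offsets × 8 distances (1–6, 8, 10 px) = 416 values, plus Gabor
  energy (mean modulus of the complex response) at 4 orientations ×
  9 wavelengths = 36.

Exact parity with any particular feature-extraction software is
explicitly not claimed. Non-finite values from degenerate inputs
(zero-variance patches, offsets exceeding the mask) become the sentinel
0, so every feature vector is finite. Haralick entropies use the natural
logarithm with $0\log 0 = 0$.

## Linear SVM classification

The decision function is the linear score $Y = w \cdot x + b$. Features
are z-scored by a standardizer fitted on training rows only — with 548
features on heterogeneous scales an unscaled linear SVM is dominated by
the largest-variance features, so scaling is the defensible default (it
can be disabled). The weights are obtained by dual coordinate descent on
the L2-regularized hinge loss with the standard shrinking heuristic; the
bias is an implicit unit feature. Numerical choices: `C = 1`,
duality-gap tolerance 0.1, a 300-epoch cap (near-chance problems have a
slow dual tail whose exact optimum is irrelevant to the reported
accuracy), and a seeded deterministic coordinate order, so identical
inputs give identical models. Tests verify the fitted hyperplane against
an independent SVM implementation on small problems.

Accuracy is $A = (X_1 + X_2)/N$ — correctly assigned incidences per
class over the test size — estimated by stratified 10-fold
cross-validation with the standardizer refitted inside each training
fold (no leakage). Classes are balanced by seeded downsampling; tie
scores ($Y = 0$) go deterministically to the control class.

The **dose-response curve** interprets the "four trials" design as the
2 × 2 pairings of the two experiments' control groups with the two
experiments' treated groups within a duration; the trial-to-trial
standard error ($n = 4$) and the mean cross-validation SE are reported
separately since the two spreads measure different things. The
**transfer matrix** trains one model per (dose, experiment) condition
and evaluates it on every condition. Each population is first split
50/50 into a training and an evaluation half, because same-experiment
conditions share their control population: a high-dimensional model
partly memorizes training controls, so scoring them again would inflate
every same-experiment cell. All cells — including the diagonal — are
therefore scored exclusively on rows no model has seen.

## Maximum mean discrepancy

The unbiased squared MMD between samples $X$ ($m$ rows) and $Y$
($n$ rows) under a Gaussian kernel
$k(x, y) = \exp(-\lVert x-y\rVert^2 / 2\sigma^2)$ is

$$\widehat{\mathrm{MMD}}^2 = \tfrac{1}{m(m-1)}\textstyle\sum_{i \ne j} k(x_i,x_j)
 + \tfrac{1}{n(n-1)}\sum_{i \ne j} k(y_i,y_j)
 - \tfrac{2}{mn}\sum_{i,j} k(x_i,y_j).$$

Design decisions, since several conventions circulate:

* the cross term uses **all $m \times n$ pairs** by default (the
  standard unbiased estimator; the two samples have unrelated indices).
  A `printed` variant that also drops the $j = i$ cross pairs — a
  literal reading of the estimator as it is sometimes typeset — is
  provided for fidelity, and the two differ by exactly the excluded
  diagonal terms (tested);
* the bandwidth defaults to the **median heuristic** over pooled
  pairwise distances (fallback: smallest nonzero distance; all-identical
  input is an error). A fixed sigma is accepted;
* since $\widehat{\mathrm{MMD}}^2$ can be negative under the null, the
  reported non-negative score is $\sqrt{\max(0, \widehat{\mathrm{MMD}}^2)}$;
  both numbers are always emitted, because published divergence bars may
  be on either scale;
* per-feature MMD standardizes each feature by the pooled mean/sd first
  (otherwise raw scale, not distribution shift, drives the ranking) and
  uses a per-feature median-heuristic bandwidth; ranking ties break by
  ascending registry index;
* the estimator is $O((m+n)^2)$, so whole-space and per-feature
  computations subsample to a seeded cap (1,000 and 500 rows per class
  by default).

The **elimination curve** removes lowest-MMD features first and reports
10-fold CV accuracy on a descending log-spaced grid of retained feature
counts, holding folds and seed fixed so the full-feature point equals
the unrestricted cross-validation exactly.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains the stages from a single validated `run_config()`
and emits the full result surface (per-dose accuracy, score histograms,
whole-space MMD per dose, per-feature MMD across repeats at each
experiment's argmax dose, elimination curve, transfer matrix) with a
seed/size fingerprint. Two runs from the same config are identical.
`validate_config()` returns findings (missing seeds, n < 2, unknown
doses, out-of-range grids) rather than throwing.

The package's own validation studies use 1,000 cells per condition for
study-level checks and 2,000 per class for the null-calibration study
(20 independent repetitions), with 10,000 per condition available by
configuration to mirror a full-scale acquisition campaign. At desk
scale the headline large-sample numbers of a real campaign (e.g. >90%
accuracy retained after removing 400+ features at 10,000 cells per
condition) are approached but not matched — at 1,000 cells per condition
the full-548-feature accuracy at the peak dose is typically ~0.82 and
the elimination curve peaks ~0.90 near 50–100 retained features;
the qualitative structure (argmax dose, duration ordering, cross-repeat
feature consistency) is what the tests assert.

## Known limitations

* The feature registry reproduces the taxonomy and counts of
  CellProfiler-style profiling, not any tool's exact values.
* The table-path generator is feature-independent multivariate normal;
  real morphological features are correlated and heavy-tailed, so
  real-data accuracy at a given effect size will differ.
* Segmentation assumes one dominant, roughly star-convex cell per
  frame; debris, doublets and out-of-focus blur are not modelled.
* MMD hypothesis-test thresholds (asymptotic or permutation nulls) are
  out of scope; the package reports effect sizes, not p-values.
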