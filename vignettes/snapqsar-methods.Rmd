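---
title: "Methods: image-based QSAR from multi-angle molecular snapshots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based QSAR from multi-angle molecular snapshots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The method

snapqsar builds a quantitative structure-activity relationship (QSAR)
classifier that never sees a molecular descriptor. Each compound is
represented by *pictures*: its 3D ball-and-stick model is photographed at a
grid of rotations about the x-, y- and z-axes, an image classifier is trained
on the snapshots, and the per-image probabilities are aggregated back to the
molecule. The pipeline is

1. **Curation.** SMILES records with a PubChem-style 0-100 activity score are
   deduplicated on canonical structure, stripped to their largest organic
   fragment (salts), and filtered to organic (carbon-containing) compounds.
   Compounds with score 40-100 are labeled active, 0-39 inactive. The score
   itself is the percent-activity normalization of reporter-assay well values,
   `100 (V_compound - V_dmso) / (V_pos - V_dmso)`.
2. **Conformers.** One low-energy conformer per molecule: ETKDG
   distance-geometry embedding with an explicit random seed followed by MMFF94
   force-field minimization (RDKit, driven through a bundled helper script).
   The same seed reproduces coordinates bit for bit, and the minimized MMFF94
   energy is stored next to the pre-minimization energy so the
   "minimization never increases energy" invariant is checkable.
3. **Snapshots.** A self-contained software rasterizer draws the conformer as
   depth-sorted shaded spheres (CPK colors, van der Waals radii x 0.3) and
   half-colored bond cylinders, orthographically projected with fit-to-frame
   scaling and a 10% margin, one fixed directional light, Lambert shading.
   For an angle increment θ the per-axis angle set is every multiple of θ in
   [0°, 360°), and the snapshot set is the full Cartesian product over the
   three axes — m³ images for m per-axis angles.
4. **Split.** Molecules (never individual images) are assigned to
   train/valid/test partitions by largest-remainder apportionment of the
   ratio, stratified by label.
5. **Training.** A small CNN is trained by SGD with momentum 0.9 on
   class-weighted cross-entropy for at most 30 epochs; training stops early
   after `patience` epochs without validation-loss improvement and the
   checkpoint is restored from the epoch with the lowest validation loss.
6. **Evaluation.** Per-image probabilities are aggregated per molecule by the
   median; the classification cutoff θ is the maximizer of Youden's
   J = sensitivity + specificity − 1 over observed scores; the report carries
   sensitivity, specificity, BAC, accuracy, precision, recall, F, MCC,
   rank-based ROC AUC, PR AUC (average precision) and cross-entropy loss.
7. **Sweeps.** Angle, split-ratio, learning-rate and batch-size grids are run
   with replicate seeds (defaults: 3 replicates, 2 for learning-rate
   conditions) and summarized per metric as mean ± sample SD across
   conditions plus the extremum and its condition.

## Design choices that were genuinely open

**Rotation convention.** Axes are named but no order is canonical; we fix
intrinsic x → y → z and document it. Snapshot counts and determinism are
unaffected by this choice.

**Renderer.** A hand-written orthographic rasterizer instead of a system
viewer (PyMOL/Jmol class tools) because bit-exact reproducibility across
machines is a test invariant: identical inputs must give identical PNG bytes.
The light direction and ambient term (0.35) are constants of the package.
With the default black background, the darkest shaded foreground color is
well above zero in every channel, which is what makes the
"changing the background recolors exactly the old-background pixels" property
hold exactly.

**Conformer generation.** Embedding must be seed-deterministic; we use
distance-geometry (ETKDG) plus MMFF94 minimization with a retry cap of five
incremented seeds. "Inorganic" is operationalized as *zero carbon atoms* —
the simplest reproducible proxy. Stereochemistry is retained, so distinct
stereoisomers stay distinct records; duplicate detection happens on canonical
SMILES after salt stripping.

**Split unit and stratification.** Rotated views of one molecule are
near-duplicates; splitting by image would leak them across partitions, so the
molecule is the split unit. Stratification by label is on by default
(`stratify = FALSE` is available): at sub-percent active rates an
unstratified split regularly produces partitions with no actives at all.
When the rare class has at least as many members as there are partitions,
each partition is guaranteed one — a partition without both classes cannot be
evaluated (Youden and AUC are undefined), and the adjustment stays within one
molecule of the proportional share in all ordinary ratios. A held-out test
set can be pinned across ratio changes via `test_ids`, so the external test
partition stays permanently fixed while train/valid are re-split.

**Classifier.** No deep-learning framework is available to the package, so
the two desk-scale architectures and their training loop are plain R matrix
code behind a registry (`tinycnn`, `pixelnet`); GoogLeNet-scale fidelity is
explicitly not a goal. `tinycnn` is one 5×5 stride-2 convolution with 64
filters, ReLU, *global mean pooling* per filter, and a linear softmax head:

* Global pooling makes the features position-invariant color/texture
  statistics. For CPK-colored snapshots the discriminative information is
  exactly of that kind ("how much blue-bonded-to-red is in the image"), and a
  64-dimensional head can be estimated from the handful of active molecules a
  5%-active library provides. Deeper stacks added nothing at desk scale and
  optimize poorly within a 30-epoch budget, so the one-block design is the
  default.
* The first eight filters are initialized with deterministic color-opponent
  and luminance kernels (R−G, B−G, ..., the basis early vision layers
  converge to anyway); the rest start from He noise. This removes the
  luck-of-the-draw dependence on random filters containing a usable color
  direction, while everything remains trainable.
* Before the first epoch, per-filter scales are calibrated on a sample of
  training images (LSUV-style data-dependent initialization): unit-variance
  pre-activations, centered biases, standardized pooled features. This places
  learning rates around 10⁻³ — the middle of the grid the method is meant to
  sweep — in the effective regime for plain SGD.
* Class imbalance is handled by inverse-frequency class weights in the
  training objective. The recorded history and the early-stopping monitor use
  the *unweighted* validation cross-entropy: with one or two active molecules
  in a validation partition, a weighted monitor is dominated by single
  molecules and stops training essentially at random.
* Patience defaults to 5 epochs; `patience = 0` disables early stopping.

**Cutoff fitting.** The Youden cutoff is fitted on the partition being
reported (`theta = NULL`), matching a per-evaluation index; passing the
validation-set cutoff to `evaluate()` reuses it instead. The prediction rule
at θ is inclusive (active iff score ≥ θ), and ties in J break toward the
smallest θ.

**ROC AUC estimators.** The primary estimator is the rank-based
(Mann-Whitney) AUC with ties counted ½. A second, threshold-weighted
estimator (`roc_auc_threshold_weighted`) averages precision-difference
weights over the active points; its printed formulation is ambiguous at the
boundary, so the package fixes one convention — ascending unique-score
thresholds, the precision sequence extended with `prec_0 = prec_1` below and
0 above, and no additional normalization by the threshold count since the
centered differences already telescope to a discrete integral — and returns
every intermediate (thresholds, precisions, weights, per-point sums) for
inspection. Under this convention the estimator is translation-invariant but
*not* comparable to the rank-based AUC: on a perfectly separated two-level
score set it evaluates to 0 because the above-grid boundary forces the last
weight negative. It is retained for inspection only and never feeds a
report.

**Multi-category Youden.** Only the binary specialization
(J = sensitivity + specificity − 1) is implemented; the k-category
generalization is out of scope.

## The synthetic fixture

`generate_library()` emulates a single-assay screening library: 0-100 scores
with heavy class imbalance and a structure-activity rule a CNN can learn from
images. Two parametric SMILES families carry the rule: nitro-substituted
aromatics (active; the nitro group is a red/blue cluster in CPK colors) and
pure hydrocarbons — alkanes, branched alkanes, cycloalkanes, alkenes and
alkylbenzenes (inactive; grey/white only). Substituents on the active family
are short (≤5 carbons) so that after fit-to-frame scaling the nitro cluster
remains a sizeable fraction of the image; alkylbenzenes in the inactive
family keep aromatic rings present in both classes, so the label is carried
by the nitro colors, not by "has a ring". Scores are *generated through* the
percent-activity equation — each record carries simulated well values whose
normalization reproduces its score to machine precision — with family
nominals 75 (active) and 8 (inactive) and truncated Gaussian noise
(default SD 10) confined to the label's score band. The realized active
count is a binomial draw clamped to two binomial SDs around
`n × active_fraction`. The default 5% active rate matches the upper end of
typical nuclear-receptor screening assays (sub-1% rates occur too and remain
available via `active_fraction`).

What the fixture does *not* emulate: real chemistry-activity relationships
(the rule is a visual chromophore, not pharmacology), conformational
ensembles, assay noise structure, or Tox21 chemical diversity. A model that
aces the fixture has demonstrated that the pipeline — rendering, splitting,
weighting, early stopping, aggregation, cutoff and metrics — is wired
correctly and that the featurization carries learnable signal; it says
nothing about predictive performance on real screening data.

`generate_separable_imageset()` is the balanced variant used by trainer
tests; at generation time a linear pixel baseline (ridge logistic model on
three global color-opponent pixel functionals — mean R−G, mean B−G, mean
luminance; each a fixed linear map of the raw pixels) must reach 95% holdout
accuracy, otherwise generation fails. This guards every downstream test
against an uninformative fixture, independently of the CNN.

## Problem sizes and numerical choices

The package's own experiments run at desk scale: libraries of 200 molecules
(5% active), 64×64-pixel renders downsampled to 32×32 classifier inputs, a
single snapshot per molecule (θ = 360°) for end-to-end runs, and 30-epoch
budgets; sweep examples use smaller libraries with the `pixelnet`
architecture. These sizes exercise every code path while keeping a complete
run in the tens of seconds. Other numerical conventions:

* median of an even number of image probabilities = mean of the middle two;
* MCC with a zero denominator is defined as 0;
* split-size rounding uses largest remainder with ties resolved
  train → valid → test;
* percentages are reported to 2 decimals, counts as integers, cross-assay
  dispersion is the sample (n−1) SD;
* probabilities are clipped to [10⁻¹², 1 − 10⁻¹²] inside cross-entropy;
* sweep replicates are averaged within condition before the across-condition
  mean ± SD is formed, and sweep caching keys on a hash of the full
  condition configuration.

## Known limitations

* The renderer is a flat-shaded z-buffer rasterizer; there is no
  anti-aliasing (deliberately — exact pixel equalities are test invariants),
  no perspective camera and no ray tracing.
* The trainer is CPU-bound pure R; it is sized for hundreds of images, not
  the millions a full multi-angle screening run would produce.
* Single conformer per molecule; no protonation-state or tautomer
  enumeration.
* The threshold-weighted AUC variant is a faithful transcription of an
  ambiguous estimator and should not be used as a performance metric.
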