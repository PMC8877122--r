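# snapqsar

Image-based QSAR for agonist/antagonist screening data.

Most quantitative structure–activity relationship (QSAR) models feed
hand-chosen molecular descriptors to a learner. snapqsar instead lets a
convolutional classifier extract its own features from *pictures of the
molecule*: each compound's MMFF94-minimized 3D ball-and-stick model is
photographed at a grid of rotation angles about the x-, y- and z-axes, a CNN
is trained on the snapshots, and per-image probabilities are aggregated back
to compounds for classification. The package targets screening-style inputs —
SMILES plus a PubChem-style 0–100 activity score per compound, with heavy
class imbalance (typically < 6 % actives) — and is written for
cheminformaticians who want a fully reproducible, desk-scale implementation
of this featurization with the complete evaluation machinery around it.

## The method in brief

* **Labels.** Activity scores are the percent-activity normalization of
  reporter-assay wells, `100·(V_compound − V_dmso)/(V_pos − V_dmso)`;
  compounds scoring 40–100 are *active*, 0–39 *inactive*.
* **Featurization.** One seed-deterministic conformer per molecule
  (distance-geometry embedding + MMFF94 minimization), rendered by a
  built-in rasterizer as CPK-colored ball-and-stick PNGs. For an angle
  increment θ the snapshot set is the Cartesian product of all multiples of
  θ in [0°, 360°) over the three axes — m³ images per molecule.
* **Training.** SGD with momentum on class-weighted cross-entropy, at most
  30 epochs, early stopping on validation loss, and the checkpoint restored
  from the lowest-validation-loss epoch. Molecules, never images, are split
  train/valid/test (stratified, largest-remainder apportionment).
* **Evaluation.** Per-molecule score = median of its image probabilities;
  the cutoff θ maximizes Youden's J = sensitivity + specificity − 1; the
  report carries sensitivity, specificity, balanced accuracy, accuracy,
  precision, recall, F, Matthews correlation, rank-based ROC AUC, PR AUC
  and cross-entropy loss.
* **Sweeps.** Replicated grids over angle, split ratio, learning rate and
  batch size, summarized as mean ± SD / extremum / arg-extremum per metric.

A synthetic-fixture module generates libraries with an image-learnable
structure–activity rule (nitroaromatic ⇒ active) and realistic imbalance, so
the entire pipeline is testable without any external downloads. See
`vignettes/snapqsar-methods.Rmd` for the full methods account.

## Worked example

```r
library(snapqsar)

# a 200-compound screening-style library, 5% active, fully deterministic
lib <- generate_library(n_molecules = 200, active_fraction = 0.05, seed = 42)
head(lib[, c("id", "smiles", "activity_score", "label")], 4)
#>        id            smiles activity_score    label
#> 1 MOL0001 CCC(C)CCCCCCCCCCC       9.216726 inactive
#> 2 MOL0002         C1CC1CCCC      24.023170 inactive
#> 3 MOL0003        CCC(CC)CCC       1.209250 inactive
#> 4 MOL0004      CC1CCCC(C)C1       9.777526 inactive
sum(lib$label == "active")
#> [1] 14

# embed -> snapshot -> split 7:1:2 -> train tinycnn -> evaluate the test set
res <- run_experiment(lib, experiment_config(), seed = 42)
res$selected_epoch      # lowest-validation-loss epoch (early stopping at 27)
#> [1] 22
res$report_test
#> <metrics_report>
#>   theta (Youden) 0.9754 | confusion tp=3 fp=0 tn=37 fn=0
#>   sens 1.000 spec 1.000 bac 1.000 acc 1.000 prec 1.000 f 1.000 mcc 1.000
#>   roc_auc 1.000 pr_auc 1.000 loss 0.018
```

The report reads: on the 40 held-out test molecules (3 active) the Youden
cutoff 0.975 classifies every molecule correctly; the rank-based ROC AUC of
1.0 says every active outranked every inactive. On this
separable-by-construction fixture that is the expected outcome — it verifies
the pipeline's wiring, not real-world predictive power.

Individual stages are exposed as ordinary functions (`parse_library`,
`curate`, `embed_library`, `snapshot_molecule`, `split_dataset`, `train`,
`evaluate`, `run_sweep`, ...), and `inst/cli/snapqsar.R` is a thin command-line
front end over them (`fixtures`, `prep`, `snap`, `split`, `run`).

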