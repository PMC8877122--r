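# Synthetic molecule libraries with an image-learnable structure-activity
# rule. Two parametric SMILES families carry the label: nitro-substituted
# aromatics (active) versus plain aliphatics (inactive). In CPK coloring the
# nitro group is a distinctive red/blue cluster on a grey ring, so the
# rendered image genuinely carries the activity signal. Class imbalance
# defaults to 5% active, the upper end of what nuclear-receptor screening
# assays typically show; scores are routed through the percent-activity
# normalization so they are consistent with simulated well values.

alkyl <- function(k) strrep("C", k)

# deterministic pool of hydrocarbon (inactive-family) SMILES,
# canonical-unique. Hydrocarbons render as grey/white only, so the
# red/blue nitro cluster of the active family is the image cue that
# carries the label.
inactive_pool <- function() {
  linear <- alkyl(2:24)
  methyl <- unlist(lapply(4:15, function(L) {
    vapply(2:min(4, L - 1), function(p) {
      paste0(alkyl(p - 1), "C(C)", alkyl(L - p))
    }, character(1))
  }))
  dimethyl <- unlist(lapply(5:14, function(L) {
    c(paste0("CC(C)", alkyl(L - 4), "C(C)C"),
      paste0("CC(C)C(C)", alkyl(L - 4)))
  }))
  ethyl <- unlist(lapply(6:14, function(L) {
    paste0(alkyl(2), "C(CC)", alkyl(L - 5))
  }))
  quat <- paste0("CC(C)(C)", alkyl(1:10))
  rings <- c(paste0("C1CCCCC1", alkyl(0:10)),
             paste0("C1CCCC1", alkyl(0:10)),
             paste0("CC1CCCCC1", alkyl(1:6)),
             paste0("C1CCCCCC1", alkyl(0:5)),
             paste0("C1CC1", alkyl(1:8)),
             paste0("C1CCC1", alkyl(1:8)),
             paste0("CC1CCC(", alkyl(1:6), ")CC1"),
             "CC1CCCC(C)C1", "CC1CCCCC1C")
  alkenes <- c(paste0("C=C", alkyl(2:12)), paste0("CC=C", alkyl(2:10)))
  # alkylbenzenes keep an aromatic ring in the inactive family too, so the
  # classes differ by the nitro colors rather than by "has a ring"
  aromatics <- c(paste0("c1ccccc1", alkyl(1:12)),
                 paste0("Cc1ccc(", alkyl(1:8), ")cc1"),
                 paste0("Cc1cccc(", alkyl(1:8), ")c1"),
                 "Cc1ccccc1C", "Cc1cc(C)cc(C)c1",
                 paste0("c1ccc2ccccc2c1", alkyl(0:4)))
  dimethyl2 <- unlist(lapply(6:13, function(L) {
    c(paste0("CC(C)", alkyl(L - 5), "C(C)CC"),
      paste0(alkyl(2), "C(C)", alkyl(L - 5), "C(C)C"))
  }))
  pool <- c(linear, methyl, dimethyl, dimethyl2, ethyl, quat, rings,
            alkenes, aromatics)
  can <- canonical_smiles(pool)
  pool[!is.na(can) & !duplicated(can)]
}

# deterministic pool of nitroaromatic (active-family) SMILES
active_pool <- function() {
  # substituents stay short so the nitro cluster remains a sizeable image
  # fraction after fit-to-frame scaling (the image must carry the label)
  # substituents are restricted to C/H/O so the red/blue nitro cluster stays
  # the one consistent color cue of the active family (no green halogens,
  # no yellow sulfur)
  subst <- c(alkyl(1:5), "O", "OC", "CO", "OCC", "C(C)C", "CC(C)C",
             "OC(C)C", "CC(C)O", "CCO", "OCCC", "C(C)O", "OCC(C)C",
             "CC(C)CO")
  pool <- c("O=[N+]([O-])c1ccccc1",
            paste0("O=[N+]([O-])c1ccc(", subst, ")cc1"),   # para
            paste0("O=[N+]([O-])c1cccc(", subst, ")c1"),   # meta
            paste0("O=[N+]([O-])c1ccccc1", subst),         # ortho
            "O=[N+]([O-])c1ccc(cc1)[N+](=O)[O-]",
            "O=[N+]([O-])c1cccc(c1)[N+](=O)[O-]",
            "Cc1ccc([N+](=O)[O-])cc1C",
            "Cc1cc(C)cc([N+](=O)[O-])c1",
            "O=[N+]([O-])c1cc(C)cc(C)c1",
            paste0("O=[N+]([O-])c1ccc(", alkyl(1:4), ")c(C)c1"),
            "O=[N+]([O-])c1cccc2ccccc12",
            "O=[N+]([O-])c1ccc2ccccc2c1",
            "O=[N+]([O-])c1ccco1",
            "O=[N+]([O-])c1ccncc1", "O=[N+]([O-])c1cccnc1")
  can <- canonical_smiles(pool)
  pool[!is.na(can) & !duplicated(can)]
}

# one-sided truncated normal by rejection (deterministic under set.seed)
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate a synthetic molecule library
#'
#' Draws molecules from two parametric SMILES families --- nitro-substituted
#' aromatics (active) and aliphatic chains/rings (inactive) --- and assigns
#' activity scores through the percent-activity normalization: each record
#' gets simulated well values whose [percent_activity()] equals its score
#' exactly. Active-family nominal score is 75, inactive-family 8, each
#' perturbed by truncated Gaussian noise that keeps actives in `[40, 100]`
#' and inactives in `[0, 39]`, so labels are consistent with the
#' activity-score threshold by construction. The realized active count is a
#' binomial draw clamped to a two-standard-deviation band around
#' `n * active_fraction`. The same seed always reproduces the same library,
#' and the library passes [curate()] unchanged (no duplicates, no
#' inorganics, single fragments).
#'
#' @param n_molecules Library size (>= 10).
#' @param active_fraction Nominal active fraction in `(0, 1)`.
#' @param score_noise_sd Standard deviation of the score noise (>= 0); `0`
#'   gives every molecule its family's nominal score.
#' @param seed Integer seed.
#' @return Molecule library `data.frame` with columns `id`, `smiles`,
#'   `activity_score`, `label`, `family`, and the simulated well values
#'   `v_compound`, `v_dmso`, `v_pos`.
#' @export
generate_library <- function(n_molecules = 200L, active_fraction = 0.05,
                             score_noise_sd = 10, seed = 1L) {
  stopifnot(n_molecules >= 10, active_fraction > 0, active_fraction < 1,
            score_noise_sd >= 0)
  if (active_fraction * n_molecules < 1) {
    stop("infeasible: active_fraction * n_molecules < 1")
  }
  set.seed(seed)
  mu <- n_molecules * active_fraction
  band <- 2 * sqrt(n_molecules * active_fraction * (1 - active_fraction))
  n_active <- stats::rbinom(1, n_molecules, active_fraction)
  n_active <- min(max(n_active, max(1, ceiling(mu - band))), floor(mu + band),
                  n_molecules - 1)
  n_inactive <- n_molecules - n_active

  act_smiles <- active_pool()
  inact_smiles <- inactive_pool()
  if (n_active > length(act_smiles) || n_inactive > length(inact_smiles)) {
    stop("fixture SMILES pools exhausted: need ", n_active, "/", n_inactive,
         ", have ", length(act_smiles), "/", length(inact_smiles))
  }
  smiles <- c(sample(act_smiles)[seq_len(n_active)],
              sample(inact_smiles)[seq_len(n_inactive)])
  family <- rep(c("nitroaromatic", "aliphatic"), c(n_active, n_inactive))

  target <- c(rtrunc_norm(n_active, 75, score_noise_sd, 40, 100),
              rtrunc_norm(n_inactive, 8, score_noise_sd, 0, 39))
  v_dmso <- 5
  v_pos <- 105
  v_compound <- v_dmso + target / 100 * (v_pos - v_dmso)
  score <- percent_activity(v_compound, v_dmso, v_pos)

  ord <- sample(n_molecules)
  df <- data.frame(id = sprintf("MOL%04d", seq_len(n_molecules)),
                   smiles = smiles[ord],
                   activity_score = score[ord],
                   label = label_activity(score[ord]),
                   family = family[ord],
                   v_compound = v_compound[ord],
                   v_dmso = v_dmso, v_pos = v_pos,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Generate a separable labeled image set
#'
#' Renders `n_per_class` molecules from each structural family at a single
#' rotation (angle increment 360°) and verifies at generation time that the
#' two classes are separable by a pixel-level linear baseline: a
#' ridge-regularized logistic model fit on half the flattened downsampled
#' pixels must reach at least 0.95 holdout accuracy, otherwise generation
#' fails. This guards every downstream trainer test against an uninformative
#' fixture.
#'
#' @param n_per_class Images per class (>= 10).
#' @param image_size Rendered image side length in pixels.
#' @param seed Integer seed (embedding and baseline split).
#' @param baseline_check Run the linear-baseline separability check.
#' @return An [image_dataset()] with per-image molecule ids; attribute
#'   `baseline_accuracy` carries the holdout accuracy of the linear baseline
#'   (`NA` if the check was skipped).
#' @export
generate_separable_imageset <- function(n_per_class = 60L, image_size = 64L,
                                        seed = 1L, baseline_check = TRUE) {
  stopifnot(n_per_class >= 10)
  act <- active_pool()[seq_len(n_per_class)]
  inact <- inactive_pool()[seq_len(n_per_class)]
  lib <- data.frame(
    id = sprintf("FIX%04d", seq_len(2 * n_per_class)),
    smiles = c(act, inact),
    label = rep(c("active", "inactive"), each = n_per_class))
  confs <- embed_library(lib, seed = seed)
  if (length(confs) < nrow(lib)) {
    stop("fixture generation failed: ", nrow(lib) - length(confs),
         " molecule(s) did not embed")
  }
  style <- render_style(image_size = image_size)
  x <- array(0, c(nrow(lib), image_size, image_size, 3))
  for (i in seq_along(confs)) {
    x[i, , , ] <- render_snapshot(confs[[i]], c(0, 0, 0), style)
  }
  ds <- image_dataset(x, lib$label, ids = lib$id)
  acc <- NA_real_
  if (baseline_check) {
    acc <- linear_baseline_accuracy(ds, seed = seed)
    if (acc < 0.95) {
      stop("fixture generation failed: linear pixel baseline accuracy ",
           round(acc, 3), " < 0.95; classes are not separable enough")
    }
  }
  attr(ds, "baseline_accuracy") <- acc
  ds
}

#' Holdout accuracy of a linear pixel baseline
#'
#' Fits a regularized logistic model on three linear pixel functionals of
#' each image --- the global means of the color-opponent channels R-G and
#' B-G and of the luminance --- using half the images (random split) and
#' reports accuracy on the other half. Each feature is a fixed linear map of
#' the raw pixels (global average pooling composed with a color-space
#' rotation), so the whole baseline is a linear model on pixels; the
#' opponent basis just makes the color statistic estimable from a few dozen
#' images. Used as an independent check that an image set is linearly
#' separable, e.g. before training a CNN on it.
#'
#' @param ds An [image_dataset()].
#' @param seed Integer seed (split shuffling).
#' @return Holdout accuracy in `[0, 1]`.
#' @export
linear_baseline_accuracy <- function(ds, seed = 1L) {
  stopifnot(inherits(ds, "image_dataset"))
  n <- dim(ds$x)[1]
  feat <- t(apply(ds$x, 1, function(im) {
    c(mean(im[, , 1] - im[, , 2]),            # R - G
      mean(im[, , 3] - im[, , 2]),            # B - G
      mean(im))                               # luminance
  }))
  y <- factor(ds$y, levels = c("inactive", "active"))
  set.seed(seed)
  ord <- sample(n)
  tr <- ord[seq(1, n, by = 2)]
  te <- ord[seq(2, n, by = 2)]
  fit <- suppressWarnings(
    glmnet::glmnet(feat[tr, ], y[tr], family = "binomial", alpha = 0,
                   lambda = 0.01))
  pred <- predict(fit, feat[te, ], type = "class")
  mean(pred == as.character(y[te]))
}
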