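# End-to-end experiment: curate -> embed -> snapshot -> split -> train ->
# evaluate. This is the unit the parameter sweep repeats per condition and
# seed.

#' Experiment configuration
#'
#' @param increment Snapshot angle increment in degrees.
#' @param ratio Train/valid/test split ratio, e.g. `c(7, 1, 2)`.
#' @param learning_rate,batch_size,max_epochs,patience Passed to
#'   [hyperparams()].
#' @param arch Classifier architecture name.
#' @param image_size Rendered snapshot side length in pixels.
#' @param input_size Classifier input side length (snapshots are downsampled
#'   to this).
#' @param stratify Stratify the split by label.
#' @param theta_from Fit the classification cutoff on the partition being
#'   evaluated (`"self"`) or reuse the validation-partition cutoff
#'   (`"valid"`).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(increment = 360, ratio = c(7, 1, 2),
                              learning_rate = 1e-3, batch_size = 16L,
                              max_epochs = 30L, patience = 5L,
                              arch = "tinycnn", image_size = 64L,
                              input_size = 32L, stratify = TRUE,
                              theta_from = c("self", "valid")) {
  structure(list(increment = increment, ratio = ratio,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), arch = arch,
                 image_size = as.integer(image_size),
                 input_size = as.integer(input_size), stratify = stratify,
                 theta_from = match.arg(theta_from)),
            class = "experiment_config")
}

# snapshot every conformer and load the PNGs of the given molecules
snapshot_and_load <- function(confs, ids, increment, style, input_size,
                              outdir) {
  sets <- list()
  for (cf in confs) {
    if (cf$id %in% ids) {
      sets[[cf$id]] <- snapshot_molecule(cf, increment, style, outdir)
    }
  }
  paths <- unlist(lapply(sets, function(s) s$items$path), use.names = FALSE)
  mol_of <- rep(vapply(sets, function(s) s$molecule_id, ""),
                vapply(sets, function(s) nrow(s$items), 0L))
  list(paths = paths, mol = unname(mol_of))
}

#' Run one end-to-end experiment
#'
#' Curates the library, embeds one MMFF94-minimized conformer per molecule,
#' renders the full snapshot set at the configured angle increment, splits
#' molecules (not images) into train/valid/test, trains the classifier with
#' early stopping and lowest-validation-loss selection, and evaluates the
#' valid and test partitions with per-molecule median aggregation and a
#' Youden cutoff.
#'
#' @param library Labeled molecule library data frame (e.g. from
#'   [generate_library()] or [parse_library()] + [label_library()]).
#' @param config An [experiment_config()].
#' @param seed Integer seed controlling embedding, splitting and training.
#' @param workdir Directory for snapshots (default: a session temp dir).
#' @return List with `report_test`, `report_valid` (both `metrics_report`),
#'   `history`, `selected_epoch`, `model`, `splits` and `n_images`.
#' @export
run_experiment <- function(library, config = experiment_config(), seed = 1L,
                           workdir = tempfile("snapqsar_run_")) {
  stopifnot(inherits(config, "experiment_config"))
  lib <- curate(library)
  labels <- stats::setNames(lib$label, lib$id)

  confs <- embed_library(lib, seed = seed)
  embedded <- vapply(confs, function(cf) cf$id, "")
  lib <- lib[lib$id %in% embedded, , drop = FALSE]

  splits <- split_dataset(lib, config$ratio, seed = seed,
                          stratify = config$stratify)
  style <- render_style(image_size = config$image_size)
  imgdir <- file.path(workdir, "imgs")

  part_data <- lapply(splits, function(ids) {
    sl <- snapshot_and_load(confs, ids, config$increment, style,
                            config$input_size, imgdir)
    x <- load_images(sl$paths, size = config$input_size)
    image_dataset(x, unname(labels[sl$mol]), ids = sl$mol)
  })

  hp <- hyperparams(learning_rate = config$learning_rate,
                    batch_size = config$batch_size,
                    max_epochs = config$max_epochs,
                    patience = config$patience)
  fit <- train(part_data$train, part_data$valid, hp = hp, arch = config$arch,
               seed = seed)

  report_valid <- evaluate(fit$model, part_data$valid, labels)
  theta <- if (config$theta_from == "valid") report_valid$theta else NULL
  report_test <- evaluate(fit$model, part_data$test, labels, theta = theta)

  list(report_test = report_test, report_valid = report_valid,
       history = fit$history, selected_epoch = fit$selected_epoch,
       model = fit$model, splits = splits,
       n_images = sum(vapply(part_data, function(d) dim(d$x)[1], 0L)))
}
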