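# Replicate experiments over angle / split / learning-rate / batch-size
# grids, summarized per metric as mean +/- sample SD across conditions, the
# extremum (minimum for losses, maximum otherwise) and the condition
# achieving it.

#' One condition of a parameter sweep
#'
#' @param axis Which knob the condition sets: `"angle"` (snapshot increment,
#'   degrees), `"split"` (ratio vector), `"lr"` (learning rate) or `"bs"`
#'   (batch size).
#' @param value The condition's setting (type appropriate to the axis).
#' @param replicate_seeds Integer vector of seeds; each seed is one full
#'   replicate experiment. Replicates default to 3 for angle/split conditions
#'   and 2 for learning-rate conditions.
#' @return A list of class `sweep_condition`.
#' @export
sweep_condition <- function(axis = c("angle", "split", "lr", "bs"), value,
                            replicate_seeds = NULL) {
  axis <- match.arg(axis)
  if (is.null(replicate_seeds)) {
    replicate_seeds <- seq_len(if (axis == "lr") 2L else 3L)
  }
  stopifnot(length(replicate_seeds) >= 1)
  ok <- switch(axis,
               angle = is.numeric(value) && length(value) == 1 && value > 0,
               split = is.numeric(value) && length(value) == 3,
               lr = is.numeric(value) && length(value) == 1 && value > 0,
               bs = is.numeric(value) && length(value) == 1 && value >= 1)
  if (!ok) stop("value is not valid for axis '", axis, "'")
  structure(list(axis = axis, value = value,
                 replicate_seeds = as.integer(replicate_seeds)),
            class = "sweep_condition")
}

condition_label <- function(cond) {
  val <- if (cond$axis == "split") paste(cond$value, collapse = ":") else
    format(cond$value)
  paste0(cond$axis, "=", val)
}

apply_condition <- function(config, cond) {
  switch(cond$axis,
         angle = {config$increment <- cond$value; config},
         split = {config$ratio <- cond$value; config},
         lr = {config$learning_rate <- cond$value; config},
         bs = {config$batch_size <- as.integer(cond$value); config})
}

#' Run a parameter sweep
#'
#' Executes one full experiment (see [run_experiment()]) per condition and
#' replicate seed. Per-condition failures are recorded and do not abort the
#' sweep; the sweep errors only if every condition failed. Results are cached
#' per (condition, seed) keyed on a hash of the configuration, so an
#' interrupted sweep resumes where it stopped.
#'
#' @param grid List of [sweep_condition()] objects.
#' @param library Labeled molecule library data frame.
#' @param base_config An [experiment_config()]; each condition overrides its
#'   axis.
#' @param cache_dir Optional directory for per-run result caching.
#' @param partition Which partition's report feeds the summary (`"test"` or
#'   `"valid"`).
#' @return A list of class `sweep_result` with `conditions` (per condition:
#'   label, reports, errors) and `summary` (see [summarize_sweep()]).
#' @export
run_sweep <- function(grid, library, base_config = experiment_config(),
                      cache_dir = NULL, partition = c("test", "valid")) {
  stopifnot(length(grid) >= 1)
  partition <- match.arg(partition)
  report_field <- paste0("report_", partition)
  conditions <- lapply(grid, function(cond) {
    stopifnot(inherits(cond, "sweep_condition"))
    config <- apply_condition(base_config, cond)
    reports <- list()
    errors <- character(0)
    for (seed in cond$replicate_seeds) {
      key <- rlang::hash(list(config, seed, partition))
      cache_file <- if (!is.null(cache_dir)) {
        file.path(cache_dir, paste0(key, ".rds"))
      }
      if (!is.null(cache_file) && file.exists(cache_file)) {
        reports[[as.character(seed)]] <- readRDS(cache_file)
        next
      }
      res <- tryCatch(run_experiment(library, config, seed = seed),
                      error = function(e) e)
      if (inherits(res, "error")) {
        errors <- c(errors, paste0("seed ", seed, ": ",
                                   conditionMessage(res)))
      } else {
        reports[[as.character(seed)]] <- res[[report_field]]
        if (!is.null(cache_file)) {
          dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
          saveRDS(res[[report_field]], cache_file)
        }
      }
    }
    list(label = condition_label(cond), condition = cond, reports = reports,
         errors = errors)
  })
  if (all(vapply(conditions, function(cc) length(cc$reports) == 0,
                 logical(1)))) {
    stop("sweep failed: every condition errored")
  }
  structure(list(conditions = conditions,
                 summary = summarize_sweep(conditions)),
            class = "sweep_result")
}

sweep_metrics <- c("roc_auc", "pr_auc", "bac", "acc", "f", "mcc",
                   "sensitivity", "specificity", "loss")

#' Summarize a sweep
#'
#' Replicates are first averaged within each condition; the summary across
#' conditions then reports, per metric, the mean, the sample (n-1) SD, the
#' best value (minimum for `loss`, maximum otherwise) and the condition
#' achieving it (first condition on ties, stable under report reordering
#' within conditions).
#'
#' @param conditions The `conditions` element of a `sweep_result` (a list of
#'   `list(label, reports)` entries).
#' @return `data.frame` with columns `metric`, `average`, `sd`, `best`,
#'   `best_condition`.
#' @export
summarize_sweep <- function(conditions) {
  keep <- vapply(conditions, function(cc) length(cc$reports) > 0, logical(1))
  conditions <- conditions[keep]
  if (length(conditions) == 0) stop("no successful conditions to summarize")
  per_cond <- vapply(conditions, function(cc) {
    vals <- vapply(cc$reports, function(rp)
      vapply(sweep_metrics, function(m) rp[[m]], numeric(1)),
      numeric(length(sweep_metrics)))
    rowMeans(matrix(vals, nrow = length(sweep_metrics)))
  }, numeric(length(sweep_metrics)))
  per_cond <- matrix(per_cond, nrow = length(sweep_metrics),
                     dimnames = list(sweep_metrics, NULL))
  labels <- vapply(conditions, function(cc) cc$label, "")
  do.call(rbind, lapply(sweep_metrics, function(m) {
    vals <- per_cond[m, ]
    minimize <- m == "loss"
    best_idx <- if (minimize) which.min(vals) else which.max(vals)
    data.frame(metric = m, average = mean(vals),
               sd = if (length(vals) > 1) stats::sd(vals) else 0,
               best = vals[best_idx], best_condition = labels[best_idx])
  }))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> ", length(x$conditions), " condition(s)\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a sweep summary as TSV
#'
#' @param sweep A `sweep_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_summary <- function(sweep, path) {
  utils::write.table(sweep$summary, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
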