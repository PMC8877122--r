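# Per-molecule aggregation, Youden-index cutoff selection, and the full
# metric panel: sensitivity, specificity, BAC, Acc, precision, recall, F,
# MCC, rank-based ROC AUC, a threshold-weighted ROC AUC variant, PR AUC, and
# cross-entropy loss.

#' Aggregate per-image probabilities to a per-molecule score
#'
#' The representative score of a molecule is the median of the probabilities
#' of its snapshot images (mean of the middle two for even counts).
#'
#' @param image_probs Non-empty numeric vector of per-image probabilities.
#' @return The median probability.
#' @export
aggregate_molecule <- function(image_probs) {
  if (length(image_probs) == 0) stop("no image probabilities to aggregate")
  stats::median(image_probs)
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2) {
    stop("labels are degenerate: both classes must be present")
  }
}

#' Youden-index classification cutoff
#'
#' Scans every observed score value as a candidate threshold (prediction
#' rule: active iff score >= threshold) and returns the one maximizing
#' Youden's J = sensitivity + specificity - 1. Ties break toward the smallest
#' threshold.
#'
#' @param scores Per-molecule probabilities.
#' @param labels `"active"` / `"inactive"` labels, same length.
#' @return The cutoff `theta`; attribute `youden` carries the attained J.
#' @export
youden_cutoff <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  check_two_classes(labels)
  is_act <- labels == "active"
  cands <- sort(unique(scores))
  j_vals <- vapply(cands, function(th) {
    pred <- scores >= th
    sens <- sum(pred & is_act) / sum(is_act)
    spec <- sum(!pred & !is_act) / sum(!is_act)
    sens + spec - 1
  }, numeric(1))
  best <- which.max(j_vals)  # first max = smallest theta on ties
  structure(cands[best], youden = j_vals[best])
}

#' Confusion matrix at a cutoff
#'
#' @param scores Per-molecule probabilities.
#' @param labels `"active"` / `"inactive"` labels.
#' @param theta Cutoff in `[0, 1]`; predicted active iff `score >= theta`.
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion_matrix <- function(scores, labels, theta) {
  stopifnot(theta >= 0, theta <= 1)
  is_act <- labels == "active"
  pred <- scores >= theta
  c(tp = sum(pred & is_act), fp = sum(pred & !is_act),
    tn = sum(!pred & !is_act), fn = sum(!pred & is_act))
}

#' Threshold metrics from a confusion matrix
#'
#' Computes sensitivity, specificity, balanced accuracy
#' `(sensitivity + specificity) / 2`, accuracy, precision, recall,
#' `F = 2 * recall * precision / (recall + precision)` and the Matthews
#' correlation coefficient. Degenerate denominators yield 0 (the customary
#' MCC convention) so that metrics are always defined.
#'
#' @param cm Named vector with `tp`, `fp`, `tn`, `fn` (e.g. from
#'   [confusion_matrix()]).
#' @return Named numeric vector of the metrics.
#' @export
confusion_metrics <- function(cm) {
  tp <- as.numeric(cm[["tp"]]); fp <- as.numeric(cm[["fp"]])
  tn <- as.numeric(cm[["tn"]]); fn <- as.numeric(cm[["fn"]])
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  rec <- sens
  f <- safe_div(2 * rec * prec, rec + prec)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  c(sensitivity = sens, specificity = spec, bac = (sens + spec) / 2,
    acc = safe_div(tp + tn, tp + fp + tn + fn), precision = prec,
    recall = rec, f = f, mcc = mcc)
}

#' Rank-based ROC AUC
#'
#' The Mann-Whitney U statistic normalized by the number of active/inactive
#' pairs; tied scores contribute 1/2. This is the package's primary ROC AUC
#' estimator.
#'
#' @param scores Per-molecule probabilities.
#' @param labels `"active"` / `"inactive"` labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  check_two_classes(labels)
  is_act <- labels == "active"
  r <- rank(scores, ties.method = "average")
  n_act <- sum(is_act)
  n_inact <- sum(!is_act)
  (sum(r[is_act]) - n_act * (n_act + 1) / 2) / (n_act * n_inact)
}

#' Threshold-weighted ROC AUC variant
#'
#' An alternative ROC AUC estimator that averages, over the active ("true")
#' points, indicator sums over the observed-score threshold grid weighted by
#' centered precision differences `W_t = (prec_{t+1} - prec_{t-1}) / 2`.
#' Thresholds are the sorted unique scores (ascending); the boundary
#' convention extends the precision sequence with `prec_0 = prec_1` below the
#' grid and 0 above it. Because the centered differences already telescope to
#' a discrete integral of the precision curve, no further normalization by
#' the threshold count is applied.
#'
#' This estimator is a coarse approximation and can disagree with --- and on
#' degenerate grids fall far below --- the rank-based [roc_auc()]; it is
#' provided for inspection, with all intermediates, never as the primary
#' statistic.
#'
#' @param scores Per-molecule probabilities.
#' @param labels `"active"` / `"inactive"` labels.
#' @return The estimate, with attribute `intermediates`: a list holding
#'   `n_pos`, `thresholds`, `prec` (precision at each threshold), `prec_ext`
#'   (with the boundary values), `w` (the weights) and `f` (the per-active
#'   weighted indicator sums).
#' @export
roc_auc_threshold_weighted <- function(scores, labels) {
  check_two_classes(labels)
  is_act <- labels == "active"
  n_pos <- sum(is_act)
  thr <- sort(unique(scores))
  tt <- length(thr)
  prec <- vapply(thr, function(t) {
    pred <- scores >= t
    sum(pred & is_act) / sum(pred)  # every threshold is an observed score,
  }, numeric(1))                    # so sum(pred) >= 1 always
  prec_ext <- c(prec[1], prec, 0)   # prec_0 = prec_1; prec_{T+1} = 0
  w <- (prec_ext[seq_len(tt) + 2] - prec_ext[seq_len(tt)]) / 2
  f <- vapply(which(is_act), function(j) {
    sum(w[thr <= scores[j]])
  }, numeric(1))
  structure(sum(f) / n_pos,
            intermediates = list(n_pos = n_pos, thresholds = thr, prec = prec,
                                 prec_ext = prec_ext, w = w, f = f))
}

#' Precision-recall AUC (average precision)
#'
#' Step integration of the precision-recall curve over recall: sweeping the
#' decision threshold down through the unique scores,
#' `AP = sum (R_t - R_{t-1}) * P_t`. When all scores are tied the curve is a
#' single point and the result equals the active prevalence.
#'
#' @param scores Per-molecule probabilities.
#' @param labels `"active"` / `"inactive"` labels.
#' @return AUC of the recall-vs-precision curve in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  check_two_classes(labels)
  is_act <- labels == "active"
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(is_act)
  last_recall <- 0
  ap <- 0
  for (t in thr) {
    pred <- scores >= t
    recall <- sum(pred & is_act) / n_pos
    prec <- sum(pred & is_act) / sum(pred)
    ap <- ap + (recall - last_recall) * prec
    last_recall <- recall
  }
  ap
}

#' Assemble a metrics report
#'
#' @param scores Per-molecule probabilities.
#' @param labels `"active"` / `"inactive"` labels.
#' @param theta Cutoff; when `NULL` it is fitted on these scores via
#'   [youden_cutoff()].
#' @return A list of class `metrics_report` with `theta`, the threshold
#'   metrics of [confusion_metrics()], `roc_auc`, `pr_auc`, the binary
#'   cross-entropy `loss` of the scores against the labels, and the confusion
#'   counts. The balanced-accuracy identity `bac == (sens + spec) / 2` is
#'   asserted on every report.
#' @export
metrics_report <- function(scores, labels, theta = NULL) {
  check_two_classes(labels)
  if (is.null(theta)) theta <- as.numeric(youden_cutoff(scores, labels))
  cm <- confusion_matrix(scores, labels, theta)
  m <- confusion_metrics(cm)
  stopifnot(isTRUE(all.equal(
    unname(m["bac"]), (m[["sensitivity"]] + m[["specificity"]]) / 2)))
  p <- pmin(1 - 1e-12, pmax(1e-12, scores))
  loss <- -mean(ifelse(labels == "active", log(p), log(1 - p)))
  structure(c(list(theta = theta), as.list(m),
              list(roc_auc = roc_auc(scores, labels),
                   pr_auc = pr_auc(scores, labels),
                   loss = loss, confusion = cm)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  theta (Youden) %.4f | confusion tp=%d fp=%d tn=%d fn=%d\n",
              x$theta, x$confusion[["tp"]], x$confusion[["fp"]],
              x$confusion[["tn"]], x$confusion[["fn"]]))
  cat(sprintf(
    "  sens %.3f spec %.3f bac %.3f acc %.3f prec %.3f f %.3f mcc %.3f\n",
    x$sensitivity, x$specificity, x$bac, x$acc, x$precision, x$f, x$mcc))
  cat(sprintf("  roc_auc %.3f pr_auc %.3f loss %.3f\n",
              x$roc_auc, x$pr_auc, x$loss))
  invisible(x)
}

#' Convert a metrics report to a one-row data frame
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @export
as.data.frame.metrics_report <- function(x, ...) {
  flat <- x[setdiff(names(x), "confusion")]
  cbind(as.data.frame(flat), as.data.frame(as.list(x$confusion)))
}

#' Evaluate a model on a snapshot partition
#'
#' Runs the full evaluation pipeline: per-image probabilities from the model,
#' per-molecule median aggregation, Youden cutoff selection, and the metric
#' panel. By default the cutoff is fitted on the partition being reported
#' (`theta = NULL`); pass a numeric `theta` (e.g. one fitted on the
#' validation partition) to reuse a cutoff.
#'
#' @param model A trained `snap_model`.
#' @param images An [image_dataset()] whose `ids` give the molecule of each
#'   image.
#' @param labels Named character vector of molecule labels (names are
#'   molecule ids).
#' @param theta Optional fixed cutoff.
#' @return A `metrics_report`; attribute `molecule_scores` carries the named
#'   per-molecule aggregated probabilities.
#' @export
evaluate <- function(model, images, labels, theta = NULL) {
  stopifnot(inherits(images, "image_dataset"), !is.null(images$ids),
            !is.null(names(labels)))
  probs <- predict(model, images)
  mol_scores <- tapply(probs, images$ids, aggregate_molecule)
  mols <- names(mol_scores)
  if (!all(mols %in% names(labels))) {
    stop("missing labels for molecule(s): ",
         paste(utils::head(setdiff(mols, names(labels)), 5), collapse = ", "))
  }
  scores <- as.numeric(mol_scores)
  report <- metrics_report(scores, unname(labels[mols]), theta = theta)
  attr(report, "molecule_scores") <- stats::setNames(scores, mols)
  report
}

#' Write a metrics report to JSON and TSV
#'
#' @param report A `metrics_report`.
#' @param path Output path without extension; `<path>.json` and `<path>.tsv`
#'   are written.
#' @return The two paths, invisibly.
#' @export
write_report <- function(report, path) {
  df <- as.data.frame(report)
  json <- paste0(path, ".json")
  tsv <- paste0(path, ".tsv")
  jsonlite::write_json(as.list(df), json, auto_unbox = TRUE, digits = NA)
  utils::write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(json = json, tsv = tsv))
}
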