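# Activity-score normalization, labeling threshold, assay summaries, and
# stratified train/valid/test splitting at user-chosen ratios.

#' Percent activity from reporter-assay well values
#'
#' Normalizes a compound-well value against the DMSO-only and positive-control
#' wells: `100 * (v_compound - v_dmso) / (v_pos - v_dmso)`.
#'
#' @param v_compound Compound-well value(s).
#' @param v_dmso Median DMSO-only well value(s).
#' @param v_pos Median positive-control well value(s).
#' @return Percent activity (same length as the inputs).
#' @export
percent_activity <- function(v_compound, v_dmso, v_pos) {
  if (any(v_pos == v_dmso)) {
    stop("degenerate controls: v_pos equals v_dmso")
  }
  100 * (v_compound - v_dmso) / (v_pos - v_dmso)
}

#' Label compounds from their activity score
#'
#' A compound is active when its 0-100 activity score is at least 40,
#' inactive when it is 0-39.
#'
#' @param score Numeric activity score(s) in `[0, 100]`.
#' @return Character vector of `"active"` / `"inactive"`.
#' @export
label_activity <- function(score) {
  if (any(is.na(score)) || any(score < 0) || any(score > 100)) {
    stop("activity scores must lie in [0, 100]")
  }
  ifelse(score >= 40, "active", "inactive")
}

#' Label every record of a molecule library
#'
#' @param records Molecule library data frame with an `activity_score` column.
#' @return The library with its `label` column filled via [label_activity()].
#' @export
label_library <- function(records) {
  records$label <- label_activity(records$activity_score)
  records
}

#' Summarize an assay's class balance
#'
#' @param records Labeled molecule library data frame.
#' @return `data.frame` of class `assay_summary` with `n_total`, `n_active`,
#'   `n_inactive`, `pct_active`, `pct_inactive` (percent, 2 decimals).
#' @export
summarize_assay <- function(records) {
  if (any(is.na(records$label))) stop("all records must be labeled")
  n <- nrow(records)
  n_act <- sum(records$label == "active")
  pct_act <- if (n > 0) round(100 * n_act / n, 2) else 0
  pct_inact <- if (n > 0) round(100 * (n - n_act) / n, 2) else 0
  structure(data.frame(n_total = n, n_active = n_act, n_inactive = n - n_act,
                       pct_active = pct_act, pct_inactive = pct_inact),
            class = c("assay_summary", "data.frame"))
}

#' Mean and sample SD across assay summaries
#'
#' Arithmetic mean and n-1 standard deviation of totals, active counts and
#' active percentages across two or more assays, rounded as customary in assay
#' reporting (counts to integers, percentages to 2 decimals).
#'
#' @param summaries List of [summarize_assay()] results (or a `data.frame`
#'   with the same columns, one row per assay).
#' @return `data.frame` with rows `n_total`, `n_active`, `pct_active` and
#'   columns `mean`, `sd`.
#' @export
cross_assay_stats <- function(summaries) {
  df <- if (is.data.frame(summaries)) summaries else
    do.call(rbind, summaries)
  if (nrow(df) < 2) stop("need at least 2 assay summaries")
  stat <- function(x, digits) c(mean = round(mean(x), digits),
                                sd = round(stats::sd(x), digits))
  out <- rbind(n_total = stat(df$n_total, 0),
               n_active = stat(df$n_active, 0),
               pct_active = stat(df$pct_active, 2))
  as.data.frame(out)
}

# Largest-remainder apportionment of n into parts proportional to weights;
# ties in remainder go to the earlier part.
largest_remainder <- function(n, weights) {
  quota <- n * weights / sum(weights)
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-(quota - base), seq_along(weights))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Split a molecule library into train/valid/test partitions
#'
#' Molecules (not images) are the split unit: every snapshot of a molecule
#' inherits its partition, which prevents leakage of near-identical rotated
#' views across partitions. Partition sizes follow the ratio by
#' largest-remainder apportionment (ties resolved train, then valid, then
#' test). By default the split is stratified by label, so each partition's
#' active count is within one molecule of its proportional share. The
#' assignment is keyed on sorted molecule ids, so permuting the input rows
#' with the same seed yields the same molecule-to-partition map. When the
#' rare class has at least as many members as there are partitions, every
#' partition is guaranteed at least one of them (otherwise the partition
#' could not be evaluated at all); a partition that still ends up with a
#' single class raises a warning, never an error.
#'
#' A held-out test set can be pinned across re-splits by passing `test_ids`
#' (e.g. the test partition of an earlier call): those molecules stay in
#' `test` and only the remainder is re-split between train and valid at the
#' ratio's train:valid proportions.
#'
#' @param records Labeled molecule library data frame with `id` and `label`.
#' @param ratio Integer vector `c(train, valid, test)`, all >= 1.
#' @param seed Integer seed; fixed seed gives a fixed partition.
#' @param stratify Stratify by label (default `TRUE`).
#' @param test_ids Optional character vector of molecule ids to pin to the
#'   test partition.
#' @return Named list of character-id vectors `train`, `valid`, `test`.
#' @export
split_dataset <- function(records, ratio, seed = 1L, stratify = TRUE,
                          test_ids = NULL) {
  stopifnot(length(ratio) == 3, all(ratio >= 1))
  ids <- as.character(records$id)
  if (anyDuplicated(ids) > 0) stop("molecule ids must be unique")
  labels <- records$label[order(ids)]
  ids <- sort(ids)
  if (!is.null(test_ids)) {
    test_ids <- as.character(test_ids)
    stopifnot(all(test_ids %in% ids))
    rest <- !(ids %in% test_ids)
    out <- split_core(ids[rest], labels[rest], ratio[1:2],
                      c("train", "valid"), seed, stratify)
    return(list(train = sort(out$train), valid = sort(out$valid),
                test = sort(test_ids)))
  }
  if (length(ids) < sum(ratio)) {
    stop("need at least ", sum(ratio), " molecules for ratio ",
         paste(ratio, collapse = ":"))
  }
  out <- split_core(ids, labels, ratio, c("train", "valid", "test"), seed,
                    stratify)
  lapply(out, sort)
}

# Core splitter over an arbitrary set of partitions. ids must be pre-sorted
# so the assignment depends only on the id set, not on input row order.
split_core <- function(ids, labels, weights, part_names, seed, stratify) {
  sizes <- largest_remainder(length(ids), weights)
  assign_group <- function(group_ids, group_sizes) {
    shuffled <- group_ids[sample(length(group_ids))]
    part <- rep(part_names, group_sizes)
    split(shuffled, factor(part, levels = part_names))
  }
  set.seed(seed)
  if (stratify && length(ids) > 0 && !any(is.na(labels))) {
    act <- ids[labels == "active"]
    inact <- ids[labels != "active"]
    act_sizes <- largest_remainder(length(act), sizes)
    # when the rare class could cover every partition, guarantee each one at
    # least one member; the move stays within one molecule of the
    # proportional share because only partitions with a fractional quota
    # below 1 can be at zero
    if (length(act) >= length(sizes) && any(act_sizes == 0)) {
      for (k in which(act_sizes == 0)) {
        donor <- which.max(act_sizes)
        if (act_sizes[donor] >= 2) {
          act_sizes[donor] <- act_sizes[donor] - 1L
          act_sizes[k] <- 1L
        }
      }
    }
    inact_sizes <- sizes - act_sizes
    if (any(inact_sizes < 0)) {  # more actives than inactives: flip roles
      inact_sizes <- largest_remainder(length(inact), sizes)
      act_sizes <- sizes - inact_sizes
    }
    out <- Map(c, assign_group(act, act_sizes),
               assign_group(inact, inact_sizes))
    if (any(act_sizes == 0) || any(inact_sizes == 0)) {
      warning("a partition received zero members of one class")
    }
  } else {
    out <- assign_group(ids, sizes)
  }
  lapply(out, unname)
}

#' Write / read a split manifest
#'
#' The manifest is a two-column TSV of molecule id and partition.
#'
#' @param splits Named list as returned by [split_dataset()].
#' @param path Manifest path.
#' @return `path` (write) or the splits list (read).
#' @export
write_split_manifest <- function(splits, path) {
  df <- data.frame(
    id = unlist(splits, use.names = FALSE),
    partition = rep(names(splits), lengths(splits)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lapply(split(df$id, factor(df$partition,
                             levels = c("train", "valid", "test"))), sort)
}
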