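test_that("per-molecule aggregation is the median", {
  expect_equal(aggregate_molecule(c(0.2, 0.8, 0.5)), 0.5)
  expect_equal(aggregate_molecule(c(0.2, 0.4, 0.6, 0.8)), 0.5)
  expect_equal(aggregate_molecule(0.9), 0.9)
  expect_error(aggregate_molecule(numeric(0)), "aggregate")
})

test_that("youden_cutoff finds the perfect-separation threshold", {
  th <- youden_cutoff(c(0.1, 0.2, 0.8, 0.9),
                      c("inactive", "inactive", "active", "active"))
  expect_equal(as.numeric(th), 0.8)
  expect_equal(attr(th, "youden"), 1)
  expect_error(youden_cutoff(c(0.1, 0.9), c("active", "active")),
               "degenerate")
})

# independent exhaustive-search oracle, written as plain loops
youden_oracle <- function(scores, labels) {
  best_j <- -Inf
  best_t <- Inf
  for (t in sort(unique(scores))) {
    tp <- fn <- tn <- fp <- 0
    for (i in seq_along(scores)) {
      if (labels[i] == "active") {
        if (scores[i] >= t) tp <- tp + 1 else fn <- fn + 1
      } else {
        if (scores[i] >= t) fp <- fp + 1 else tn <- tn + 1
      }
    }
    j <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (j > best_j) {
      best_j <- j
      best_t <- t
    }
  }
  c(theta = best_t, j = best_j)
}

test_that("youden_cutoff matches the exhaustive oracle on random instances", {
  for (case in 1:500) {
    d <- random_scores_labels(n = sample(5:50, 1), seed = case,
                              n_levels = sample(c(Inf, 4, 10), 1))
    th <- youden_cutoff(d$scores, d$labels)
    orc <- youden_oracle(d$scores, d$labels)
    expect_equal(as.numeric(th), unname(orc["theta"]))
    expect_equal(attr(th, "youden"), unname(orc["j"]), tolerance = 1e-12)
  }
})

test_that("confusion metrics match the printed formulas", {
  perfect <- confusion_metrics(c(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_equal(unname(perfect[c("acc", "bac", "f", "mcc")]), rep(1, 4))

  m <- confusion_metrics(c(tp = 2, fp = 1, tn = 3, fn = 0))
  expect_equal(unname(m["acc"]), 5 / 6)
  expect_equal(unname(m["precision"]), 2 / 3)
  expect_equal(unname(m["recall"]), 1)
  expect_equal(unname(m["f"]), 0.8)
  expect_equal(unname(m["mcc"]), (2 * 3 - 1 * 0) / sqrt(3 * 2 * 4 * 3))

  degen <- confusion_metrics(c(tp = 0, fp = 0, tn = 5, fn = 5))
  expect_equal(unname(degen["mcc"]), 0)
})

test_that("confusion metrics agree with direct arithmetic on random matrices", {
  set.seed(42)
  for (case in 1:1000) {
    cm <- c(tp = rpois(1, 5), fp = rpois(1, 5), tn = rpois(1, 5),
            fn = rpois(1, 5))
    m <- confusion_metrics(cm)
    tp <- cm[["tp"]]; fp <- cm[["fp"]]; tn <- cm[["tn"]]; fn <- cm[["fn"]]
    sens <- if (tp + fn == 0) 0 else tp / (tp + fn)
    spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
    expect_equal(unname(m["bac"]), (sens + spec) / 2, tolerance = 1e-12)
    den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    expect_equal(unname(m["mcc"]), mcc, tolerance = 1e-12)
    expect_gte(m[["mcc"]], -1)
    expect_lte(m[["mcc"]], 1)
  }
})

test_that("roc_auc equals the pairwise U-statistic oracle", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9),
                       c("inactive", "inactive", "active", "active")), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2),
                       c("inactive", "inactive", "active", "active")), 0)
  for (case in 1:30) {
    d <- random_scores_labels(n = sample(6:40, 1), seed = 1000 + case,
                              n_levels = sample(c(Inf, 5), 1))
    act <- d$scores[d$labels == "active"]
    inact <- d$scores[d$labels == "inactive"]
    u <- 0
    for (a in act) for (b in inact) {
      u <- u + (a > b) + 0.5 * (a == b)
    }
    expect_equal(roc_auc(d$scores, d$labels),
                 u / (length(act) * length(inact)), tolerance = 1e-12)
  }
})

test_that("roc_auc is complementary and monotone-invariant", {
  for (case in 1:20) {
    d <- random_scores_labels(30, seed = 2000 + case)  # tie-free
    a <- roc_auc(d$scores, d$labels)
    expect_equal(a + roc_auc(1 - d$scores, d$labels), 1, tolerance = 1e-12)
    expect_equal(roc_auc(plogis(5 * d$scores - 1), d$labels), a,
                 tolerance = 1e-12)
  }
})

test_that("roc_auc and pr_auc agree with pROC/independent step oracle", {
  for (case in 1:25) {
    d <- random_scores_labels(n = sample(10:60, 1), seed = 3000 + case,
                              n_levels = sample(c(Inf, 6), 1))
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = d$labels, predictor = d$scores, levels = c("inactive", "active"),
      direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(d$scores, d$labels), ref, tolerance = 1e-9)

    # independent PR step integration over descending thresholds
    ord <- order(d$scores, decreasing = TRUE)
    s <- d$scores[ord]; y <- d$labels[ord] == "active"
    ap <- 0; last_r <- 0; npos <- sum(y)
    for (t in unique(s)) {
      sel <- s >= t
      r <- sum(y & sel) / npos
      p <- sum(y & sel) / sum(sel)
      ap <- ap + (r - last_r) * p
      last_r <- r
    }
    expect_equal(pr_auc(d$scores, d$labels), ap, tolerance = 1e-9)
  }
})

test_that("pr_auc handles the boundary curves", {
  expect_equal(pr_auc(c(0.1, 0.2, 0.8, 0.9),
                      c("inactive", "inactive", "active", "active")), 1)
  expect_equal(pr_auc(rep(0.5, 10), rep(c("active", "inactive"), c(3, 7))),
               0.3)
})

test_that("the threshold-weighted ROC estimator matches hand computation", {
  # 4 points, perfectly separated: thresholds {0,1}, prec = (1/2, 1);
  # extended (1/2, 1/2, 1, 0); w = (1/4, -1/4); actives see both thresholds
  est <- roc_auc_threshold_weighted(c(0, 0, 1, 1),
                                    c("inactive", "inactive", "active",
                                      "active"))
  expect_equal(as.numeric(est), 0)
  it <- attr(est, "intermediates")
  expect_equal(it$prec, c(0.5, 1))
  expect_equal(it$w, c(0.25, -0.25))
  expect_equal(it$f, c(0, 0))

  # 4 points, one misranked: scores .1 .4 .3 .2, labels I I A A
  # thresholds .1 .2 .3 .4, prec = (1/2, 2/3, 1/2, 0);
  # extended (1/2, 1/2, 2/3, 1/2, 0, 0) -> w = (1/12, 0, -1/3, -1/4)
  est2 <- roc_auc_threshold_weighted(
    c(0.1, 0.4, 0.3, 0.2),
    c("inactive", "inactive", "active", "active"))
  it2 <- attr(est2, "intermediates")
  expect_equal(it2$prec, c(1 / 2, 2 / 3, 1 / 2, 0))
  expect_equal(it2$w, c(1 / 12, 0, -1 / 3, -1 / 4))
  # f(active at .3) = w1+w2+w3 = -1/4; f(active at .2) = w1+w2 = 1/12
  expect_equal(it2$f, c(-1 / 4, 1 / 12))
  expect_equal(as.numeric(est2), (-1 / 4 + 1 / 12) / 2)
})

test_that("the threshold-weighted estimator is translation-invariant", {
  for (case in 1:10) {
    d <- random_scores_labels(20, seed = 4000 + case)
    e1 <- as.numeric(roc_auc_threshold_weighted(d$scores, d$labels))
    e2 <- as.numeric(roc_auc_threshold_weighted(d$scores + 3.7, d$labels))
    expect_equal(e1, e2, tolerance = 1e-12)
  }
  expect_error(roc_auc_threshold_weighted(c(1, 2), rep("inactive", 2)),
               "degenerate")
})

test_that("metrics_report asserts the BAC identity and is deterministic", {
  d <- random_scores_labels(40, seed = 7)
  r1 <- metrics_report(d$scores, d$labels)
  r2 <- metrics_report(d$scores, d$labels)
  expect_identical(unclass(r1), unclass(r2))
  expect_equal(r1$bac, (r1$sensitivity + r1$specificity) / 2)
  expect_equal(sum(r1$confusion), 40)

  # a constant classifier has BAC 1/2 whatever the tie-break at theta
  rc <- metrics_report(rep(0.5, 20), rep(c("active", "inactive"), 10))
  expect_equal(rc$bac, 0.5)
})
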