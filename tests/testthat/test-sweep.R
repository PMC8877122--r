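# build a fake per-condition result from explicit molecule scores so the
# summary logic is tested independently of any training
fake_condition <- function(label, score_sets) {
  reports <- lapply(score_sets, function(s) {
    metrics_report(s, rep(c("active", "inactive"), each = length(s) / 2))
  })
  list(label = label, reports = reports, errors = character(0))
}

test_that("sweep conditions validate axis and value", {
  expect_s3_class(sweep_condition("angle", 185), "sweep_condition")
  expect_equal(sweep_condition("angle", 185)$replicate_seeds, 1:3)
  expect_equal(sweep_condition("lr", 1e-4)$replicate_seeds, 1:2)
  expect_error(sweep_condition("angle", -5), "not valid")
  expect_error(sweep_condition("split", c(1, 2)), "not valid")
})

test_that("summarize_sweep averages replicates within condition first", {
  c1 <- fake_condition("angle=360",
                       list(c(0.9, 0.8, 0.2, 0.1), c(0.7, 0.8, 0.3, 0.2)))
  c2 <- fake_condition("angle=120", list(c(0.6, 0.4, 0.5, 0.3)))
  sm <- summarize_sweep(list(c1, c2))
  roc_row <- sm[sm$metric == "roc_auc", ]

  rocs_c1 <- vapply(c1$reports, function(r) r$roc_auc, 0)
  rocs_c2 <- vapply(c2$reports, function(r) r$roc_auc, 0)
  per_cond <- c(mean(rocs_c1), mean(rocs_c2))
  expect_equal(roc_row$average, mean(per_cond), tolerance = 1e-9)
  expect_equal(roc_row$sd, sd(per_cond), tolerance = 1e-9)
  expect_equal(roc_row$best, max(per_cond), tolerance = 1e-9)
  expect_equal(roc_row$best_condition,
               c("angle=360", "angle=120")[which.max(per_cond)])
})

test_that("a single condition with one report has mean = report and sd = 0", {
  c1 <- fake_condition("lr=0.001", list(c(0.9, 0.7, 0.2, 0.4)))
  sm <- summarize_sweep(list(c1))
  expect_equal(sm[sm$metric == "bac", "average"], c1$reports[[1]]$bac)
  expect_true(all(sm$sd == 0))
})

test_that("the loss row reports the minimum, other rows the maximum", {
  c1 <- fake_condition("bs=2", list(c(0.9, 0.8, 0.1, 0.2)))   # good ranking
  c2 <- fake_condition("bs=16", list(c(0.4, 0.6, 0.5, 0.45))) # poor ranking
  sm <- summarize_sweep(list(c1, c2))
  loss_row <- sm[sm$metric == "loss", ]
  losses <- c(c1$reports[[1]]$loss, c2$reports[[1]]$loss)
  expect_equal(loss_row$best, min(losses))
  expect_equal(loss_row$best_condition, c("bs=2", "bs=16")[which.min(losses)])
  expect_equal(sm[sm$metric == "roc_auc", "best_condition"], "bs=2")
})

test_that("the arg-best condition is stable under report reordering", {
  sets <- list(c(0.9, 0.8, 0.2, 0.1), c(0.5, 0.6, 0.4, 0.45))
  c1 <- fake_condition("angle=176", sets)
  c1_rev <- fake_condition("angle=176", rev(sets))
  c2 <- fake_condition("angle=65", list(c(0.55, 0.5, 0.5, 0.5)))
  sm1 <- summarize_sweep(list(c1, c2))
  sm2 <- summarize_sweep(list(c1_rev, c2))
  expect_equal(sm1$best_condition, sm2$best_condition)
  expect_equal(sm1$average, sm2$average, tolerance = 1e-9)
  expect_error(summarize_sweep(list()), "summarize|no successful")
})

test_that("run_sweep executes conditions end-to-end and caches replicates", {
  lib <- generate_library(40, 0.2, seed = 9)
  base <- experiment_config(increment = 360, ratio = c(2, 1, 1),
                            learning_rate = 1e-2, max_epochs = 3,
                            patience = 0, arch = "pixelnet",
                            image_size = 48, input_size = 16)
  grid <- list(sweep_condition("lr", 1e-2, replicate_seeds = 1L),
               sweep_condition("lr", 1e-3, replicate_seeds = 1L))
  cache <- tempfile("sweepcache_")
  sw <- run_sweep(grid, lib, base, cache_dir = cache)
  expect_s3_class(sw, "sweep_result")
  expect_equal(length(sw$conditions), 2)
  expect_true(all(vapply(sw$conditions,
                         function(cc) length(cc$reports) == 1, logical(1))))
  expect_equal(nrow(sw$summary), length(snapqsar:::sweep_metrics))
  expect_equal(length(list.files(cache)), 2)

  # resuming from cache reproduces the summary without recomputation
  sw2 <- run_sweep(grid, lib, base, cache_dir = cache)
  expect_equal(sw$summary, sw2$summary, tolerance = 1e-12)
})

test_that("the angle axis multiplies the image count by the cube law", {
  lib <- generate_library(12, 0.3, seed = 10)
  base <- experiment_config(ratio = c(1, 1, 1), learning_rate = 1e-2,
                            max_epochs = 2, patience = 0, arch = "pixelnet",
                            image_size = 48, input_size = 16)
  r360 <- run_experiment(lib, base, seed = 1)
  base120 <- base
  base120$increment <- 120
  r120 <- run_experiment(lib, base120, seed = 1)
  expect_equal(r120$n_images, 27 * r360$n_images)
})
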