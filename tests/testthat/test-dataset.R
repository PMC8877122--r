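test_that("percent_activity implements the control-well normalization", {
  expect_equal(percent_activity(10, 10, 110), 0)
  expect_equal(percent_activity(110, 10, 110), 100)
  expect_equal(percent_activity(60, 10, 110), 50)
  expect_equal(percent_activity(c(10, 60), 10, 110), c(0, 50))
  expect_error(percent_activity(5, 7, 7), "degenerate")
})

test_that("the activity threshold is 40", {
  expect_equal(label_activity(40), "active")
  expect_equal(label_activity(39), "inactive")
  expect_equal(label_activity(0), "inactive")
  expect_equal(label_activity(100), "active")
  expect_error(label_activity(101))
  expect_error(label_activity(-1))
})

make_labeled <- function(n, n_active) {
  data.frame(id = sprintf("m%04d", seq_len(n)),
             label = rep(c("active", "inactive"), c(n_active, n - n_active)))
}

test_that("summarize_assay reproduces screening-scale percentages", {
  s <- summarize_assay(make_labeled(7537, 283))
  expect_equal(s$pct_active, 3.75)
  expect_equal(s$pct_inactive, 96.25)
  expect_equal(summarize_assay(make_labeled(7662, 67))$pct_active, 0.87)
  expect_equal(summarize_assay(make_labeled(7604, 395))$pct_active, 5.19)
  expect_equal(summarize_assay(make_labeled(50, 0))$pct_active, 0)
})

test_that("assay percentages always sum to 100 within rounding", {
  set.seed(1)
  for (i in 1:50) {
    n <- sample(50:5000, 1)
    s <- summarize_assay(make_labeled(n, sample(0:n, 1)))
    expect_lte(abs(s$pct_active + s$pct_inactive - 100), 0.01)
  }
})

test_that("cross_assay_stats gives the mean and n-1 SD with assay rounding", {
  sums <- list(summarize_assay(make_labeled(7537, 283)),
               summarize_assay(make_labeled(7662, 67)),
               summarize_assay(make_labeled(7604, 395)))
  st <- cross_assay_stats(sums)
  expect_equal(st["n_total", "mean"], 7601)
  expect_equal(st["n_total", "sd"], 63)
  expect_equal(st["n_active", "mean"], 248)
  expect_equal(st["n_active", "sd"], 167)
  expect_equal(st["pct_active", "mean"], 3.27)
  expect_equal(st["pct_active", "sd"], 2.20)

  same <- cross_assay_stats(list(sums[[1]], sums[[1]]))
  expect_equal(same["n_total", "sd"], 0)
  expect_error(cross_assay_stats(list(sums[[1]])), "at least 2")
})

test_that("split sizes follow largest-remainder apportionment", {
  six <- make_labeled(6, 2)
  # 2 actives cannot cover 3 partitions: warn, never fail
  expect_warning(sp <- split_dataset(six, c(1, 1, 1), seed = 1),
                 "zero members")
  expect_equal(lengths(sp), c(train = 2, valid = 2, test = 2))

  ten <- make_labeled(10, 3)
  sp <- suppressWarnings(split_dataset(ten, c(7, 1, 2), seed = 1))
  expect_equal(lengths(sp), c(train = 7, valid = 1, test = 2))
})

test_that("stratification keeps each partition near the global active rate", {
  lib <- make_labeled(100, 10)
  for (seed in 1:20) {
    sp <- split_dataset(lib, c(3, 1, 1), seed = seed)
    acts <- vapply(sp, function(ids)
      sum(lib$label[match(ids, lib$id)] == "active"), 0L)
    expect_true(acts[["train"]] %in% 5:7)
    expect_true(acts[["valid"]] %in% 1:3)
    expect_true(acts[["test"]] %in% 1:3)
    expect_equal(sum(acts), 10)
  }
})

test_that("split_dataset partitions: disjoint, covering, seed-stable", {
  set.seed(99)
  for (case in 1:50) {
    n <- sample(12:300, 1)
    n_act <- sample(2:max(2, n %/% 5), 1)
    ratio <- sample(1:7, 3, replace = TRUE)
    seed <- sample(1e6, 1)
    lib <- make_labeled(n, n_act)
    sp <- suppressWarnings(split_dataset(lib, ratio, seed = seed))
    all_ids <- unlist(sp, use.names = FALSE)
    expect_equal(sort(all_ids), sort(lib$id))        # coverage
    expect_false(anyDuplicated(all_ids) > 0)         # disjointness
    sp2 <- suppressWarnings(split_dataset(lib, ratio, seed = seed))
    expect_identical(sp, sp2)                        # seed stability
  }
})

test_that("the split is keyed on molecule id, not input order", {
  lib <- make_labeled(40, 8)
  sp1 <- split_dataset(lib, c(3, 1, 1), seed = 7)
  perm <- lib[sample(nrow(lib)), ]
  sp2 <- split_dataset(perm, c(3, 1, 1), seed = 7)
  expect_identical(sp1, sp2)
})

test_that("a pinned test set survives re-splitting at a new ratio", {
  lib <- make_labeled(60, 12)
  sp <- split_dataset(lib, c(3, 1, 1), seed = 2)
  re <- split_dataset(lib, c(7, 1, 2), seed = 5, test_ids = sp$test)
  expect_identical(re$test, sp$test)
  expect_equal(sort(c(re$train, re$valid)),
               sort(setdiff(lib$id, sp$test)))
  # train:valid proportions follow the new ratio
  expect_equal(length(re$train), 42)
  expect_equal(length(re$valid), 6)
})

test_that("degenerate stratification warns instead of failing", {
  lib <- make_labeled(12, 1)
  expect_warning(split_dataset(lib, c(1, 1, 1), seed = 1), "zero members")
})
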