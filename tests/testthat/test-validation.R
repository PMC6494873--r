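test_that("31 stratified individuals split into folds of sizes {7,6,6,6,6}", {
  labels <- stats::setNames(rep(c("case", "control"), c(16L, 15L)),
                            paste0("i", 1:31))
  sp <- make_splits(labels, n_folds = 5L, n_repetitions = 20L, seed = 3L)
  for (r in 1:20) {
    sizes <- sort(tabulate(sp$assignments[, r], 5L), decreasing = TRUE)
    expect_equal(sizes, c(7L, 6L, 6L, 6L, 6L))
    # per-fold class counts within 1 of proportional
    for (f in 1:5) {
      tst <- names(labels)[sp$assignments[, r] == f]
      n_case <- sum(labels[tst] == "case")
      expect_lte(abs(n_case - 16 * length(tst) / 31), 1)
    }
    # every individual tested exactly once per repetition
    expect_setequal(
      unlist(lapply(1:5, function(f) test_samples(sp, r, f))), names(labels))
  }
})

test_that("splits are deterministic under the seed and serialize bit-identically", {
  labels <- stats::setNames(rep(c("case", "control"), each = 10L),
                            paste0("i", 1:20))
  s1 <- make_splits(labels, seed = 9L, n_repetitions = 5L)
  s2 <- make_splits(labels, seed = 9L, n_repetitions = 5L)
  expect_identical(s1, s2)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_splits(s1, f1); write_splits(s2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(read_splits(f1)$assignments, s1$assignments)
  s3 <- make_splits(labels, seed = 10L, n_repetitions = 5L)
  expect_false(identical(s1$assignments, s3$assignments))
})

test_that("grouped samples stay in the same fold (paired designs)", {
  labels <- stats::setNames(rep(c("control", "case"), 8L),
                            paste0("s", 1:16))
  groups <- stats::setNames(rep(paste0("i", 1:8), each = 2L), paste0("s", 1:16))
  sp <- make_splits(labels, groups = groups, n_folds = 4L,
                    n_repetitions = 5L, seed = 2L)
  for (r in 1:5) {
    for (f in 1:4) {
      tst <- test_samples(sp, r, f)
      inds <- unique(groups[tst])
      expect_setequal(tst, names(groups)[groups %in% inds])
    }
  }
})

test_that("permutation p bound follows its exact arithmetic", {
  obs <- 0.8
  mk <- function(k) c(rep(0.9, k), rep(0.1, 1000L - k))  # k exceedances
  expect_equal(perm_p_bound(mk(0L), obs), 1 / 1000)
  expect_equal(perm_p_bound(mk(12L), obs), 13 / 1000)
  expect_equal(perm_p_bound(mk(999L), obs), 1000 / 1000)
  # observed at the null minimum: bound exceeds 1 but stays well-defined
  expect_equal(perm_p_bound(rep(0.9, 1000L), obs), 1001 / 1000)
  # denominator follows n when fewer permutations are supplied
  expect_equal(perm_p_bound(c(0.9, 0.1), obs, n = 2L), 2 / 2)
})

test_that("sensitivity and specificity follow their case/control definitions", {
  truth <- c(rep("case", 4L), rep("control", 6L))
  pred <- c("case", "case", "control", "control",
            "control", "control", "control", "control", "case", "case")
  met <- cytofuse:::cv_metrics(truth, pred, "case", "control")
  expect_equal(met$sensitivity, 2 / 4)
  expect_equal(met$specificity, 4 / 6)
  expect_equal(met$accuracy, 6 / 10)
})

test_that("double CV records one test prediction per sample per repetition", {
  ds <- tiny_study(seed = 10L, n_per_class = c(5L, 5L),
                   effects = list(case = c(popA = 2)))
  sp <- make_splits(ds$labels, groups = ds$individuals, n_folds = 5L,
                    n_repetitions = 3L, seed = 4L)
  cv <- run_double_cv(ds, tiny_config(), sp)
  expect_equal(dim(cv$y_hat), c(10L, 3L))
  expect_false(anyNA(cv$y_hat))
  expect_true(all(c(cv$accuracy, cv$sensitivity, cv$specificity) >= 0))
  expect_true(all(c(cv$accuracy, cv$sensitivity, cv$specificity) <= 1))
  # a strong abundance effect is learnable even in this tiny design
  expect_gte(cv$accuracy, 0.8)
})

test_that("training-fold fits are untouched by test-fold data", {
  ds <- tiny_study(seed = 20L, n_per_class = c(5L, 5L))
  train <- ds$samples[c(1:4, 6:9)]
  test <- setdiff(ds$samples, train)
  b1 <- fit_fold(ds, train, tiny_config())
  # replace every test-fold frame by pure noise
  ds2 <- ds
  set.seed(99)
  for (key in names(ds2$frames)) {
    fr <- ds2$frames[[key]]
    if (fr$sample_id %in% test) {
      fr$events <- matrix(stats::rnorm(length(fr$events), 50, 10),
                          nrow(fr$events))
      colnames(fr$events) <- fr$marker_names
      ds2$frames[[key]] <- fr
    }
  }
  b2 <- fit_fold(ds2, train, tiny_config())
  expect_identical(b1, b2)
})

test_that("permutation test under a null study is uninformative", {
  ds <- tiny_study(seed = 30L, n_per_class = c(5L, 5L))
  sp <- make_splits(ds$labels, groups = ds$individuals, n_folds = 5L,
                    n_repetitions = 2L, seed = 5L)
  cfg <- tiny_config()
  cv <- run_double_cv(ds, cfg, sp)
  pt <- permutation_test(ds, cfg, sp, cv$accuracy,
                         fixed_hyperparameters = list(K_ortho = 0L),
                         n_permutations = 30L, seed = 6L)
  expect_length(pt$null_accuracies, 30L)
  expect_equal(pt$p_bound,
               (sum(pt$null_accuracies >= cv$accuracy) + 1) / 30)
  expect_gt(pt$p_bound, 0.05)
})

test_that("a duplicated panel contributes nothing to the fusion accuracy", {
  ds <- tiny_study(seed = 40L, n_per_class = c(5L, 5L),
                   effects = list(case = c(popA = 1.5)))
  # duplicate panel P1 under a new aliquot id
  frames <- unname(ds$frames)
  for (fr in unname(ds$frames)) {
    if (fr$aliquot_id == "P1") {
      fr$aliquot_id <- "P1copy"
      frames[[length(frames) + 1L]] <- fr
    }
  }
  man <- ds$manifest
  man2 <- man[man$aliquot_id == "P1", ]
  man2$aliquot_id <- "P1copy"
  ds_dup <- study_dataset(frames, rbind(man, man2))
  sp <- make_splits(ds$labels, groups = ds$individuals, n_folds = 5L,
                    n_repetitions = 2L, seed = 7L)
  cfg <- tiny_config(K_ortho = 0L)
  inc <- panel_increase(ds_dup, cfg, sp)
  expect_lte(abs(inc[["P1copy"]]), 10)
  # %increase is bounded by 100 - accuracy(without d)
  acc_all <- attr(inc, "accuracy_all") * 100
  for (a in names(inc)) expect_lte(inc[[a]], 100 - (acc_all - inc[[a]]))
  expect_error(panel_increase(subset_study(ds, aliquots = "P1"), cfg, sp),
               class = "cytofuse_config_error")
})
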