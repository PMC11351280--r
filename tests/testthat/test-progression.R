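test_that("progression labels follow the ordinal better/worse/unchanged rule", {
  status <- tibble::tibble(
    subject_id = rep(c("a", "b", "c", "d"), each = 2),
    month = rep(c(42, 54), times = 4),
    status = c(1, 2,    # MCI -> dementia: worse
               2, 2,    # dementia -> dementia: unchanged
               1, 0,    # MCI -> CN: better
               0, 1))   # CN -> MCI: worse
  labs <- make_progression_labels(status, horizon_years = 1)
  got <- setNames(labs$label, labs$subject_id)
  expect_equal(got[["a"]], -1L)
  expect_equal(got[["b"]], 0L)
  expect_equal(got[["c"]], 1L)
  expect_equal(got[["d"]], -1L)
  expect_equal(attr(labs, "horizon_years"), 1)
  expect_equal(unname(attr(labs, "class_counts")), c(2L, 1L, 1L))
})

test_that("subjects without a horizon status are dropped and counted", {
  status <- tibble::tibble(
    subject_id = c("a", "a", "b"),
    month = c(42, 78, 42),
    status = c(1, 2, 1))
  expect_message(labs <- make_progression_labels(status, horizon_years = 3),
                 "dropped 1 subject")
  expect_equal(labs$subject_id, "a")
  expect_equal(attr(labs, "n_dropped"), 1L)
  expect_error(make_progression_labels(status, horizon_years = 2),
               "must be one of")
})

test_that("stratified folds deviate from proportionality by at most one", {
  withr::with_seed(1, {
    y <- factor(rep(c(-1, 0, 1), times = c(12, 25, 7)), levels = c(-1, 0, 1))
    for (rep_i in 1:10) {
      folds <- tcpca:::stratified_folds(y, 3)
      for (cl in levels(y)) {
        per_fold <- table(factor(folds[y == cl], levels = 1:3))
        expect_lte(max(per_fold) - min(per_fold), 1)
      }
    }
  })
})

test_that("a perfectly separable table scores ACC 1 with zero spread", {
  withr::with_seed(2, {
    x <- matrix(rnorm(60 * 2), 60, 2)
    y <- ifelse(x[, 1] > 0, 1L, ifelse(x[, 2] > 0, 0L, -1L))
    x[, 1] <- x[, 1] + 100 * y   # huge margins
  })
  ids <- sprintf("s%02d", 1:60)
  ft <- feature_table(x, ids, "OR")
  labs <- progression_labels(ids, y, horizon_years = 1)
  ev <- evaluate(ft, labs, classifier_spec("knn"), n_folds = 3, n_runs = 3,
                 seed = 7)
  expect_equal(ev$summary$mean[ev$summary$metric == "acc"], 1)
  expect_equal(ev$summary$sd[ev$summary$metric == "acc"], 0)
})

test_that("metrics of a constant majority predictor match the closed form", {
  # proportions 1:1:2 -> ACC 0.5, macro recall 1/3
  truth <- factor(c(-1, 1, 0, 0), levels = c(-1, 0, 1))
  pred <- factor(c(0, 0, 0, 0), levels = c(-1, 0, 1))
  m <- tcpca:::classification_metrics(truth, pred)
  expect_equal(unname(m["acc"]), 0.5)
  expect_equal(unname(m["recall"]), 1 / 3)
})

test_that("macro recall of a uniform random predictor is near 1/3", {
  withr::with_seed(5, {
    truth <- factor(sample(c(-1, 0, 1), 1000, replace = TRUE,
                           prob = c(0.1, 0.7, 0.2)), levels = c(-1, 0, 1))
    pred <- factor(sample(c(-1, 0, 1), 1000, replace = TRUE),
                   levels = c(-1, 0, 1))
  })
  m <- tcpca:::classification_metrics(truth, pred)
  expect_lt(abs(m[["recall"]] - 1 / 3), 0.05)
})

test_that("evaluate errors when a class cannot fill the folds", {
  ids <- sprintf("s%02d", 1:20)
  ft <- feature_table(matrix(rnorm(40), 20, 2), ids, "OR")
  labs <- progression_labels(ids, c(rep(0L, 18), 1L, -1L), horizon_years = 1)
  expect_error(evaluate(ft, labs, classifier_spec("knn"), n_folds = 3),
               "reduce the fold count")
})

test_that("the paired decision rule is significant iff p <= 0.01 and T > 2", {
  # all-zero differences: not significant, degenerate
  t0 <- paired_model_test(rep(0.6, 10), rep(0.6, 10))
  expect_false(t0$significant)
  expect_true(t0$degenerate)

  # constant positive differences: significant, degenerate
  tpos <- paired_model_test(rep(0.7, 10), rep(0.6, 10))
  expect_true(tpos$significant)
  expect_true(tpos$degenerate)

  # clear positive shift with noise: one-sided power near 1
  withr::with_seed(11, {
    b <- runif(30, 0.5, 0.7)
    a <- b + 0.05 + rnorm(30, sd = 0.01)
  })
  tshift <- paired_model_test(a, b)
  expect_true(tshift$significant)
  expect_gt(tshift$statistic, 2)
  expect_lte(tshift$p_value, 0.01)

  # all-negative differences: never significant under the one-sided rule
  tneg <- paired_model_test(b - 0.05, b)
  expect_false(tneg$significant)
  expect_error(paired_model_test(1:3, 1:4), "equal length")
})

test_that("evaluation reports are byte-identical under a shared master seed", {
  sim <- generate_cohorts(synthetic_spec(n_target = 60, n_background = 30,
                                         p = 3, k = 8,
                                         label_proportions = c(`-1` = 1, `0` = 2, `1` = 1),
                                         seed = 13))
  ft <- represent(sim$pair, "sor")
  run <- function() evaluate(ft, sim$truth$labels, classifier_spec("rf", num_trees = 30),
                             n_folds = 3, n_runs = 10, seed = 99)
  expect_identical(run(), run())
})

test_that("the comparison grid shares folds across methods and counts cells", {
  sim <- generate_cohorts(synthetic_spec(n_target = 72, n_background = 40,
                                         p = 4, k = 10,
                                         label_proportions = c(`-1` = 1, `0` = 2, `1` = 1),
                                         subtype_separation = 6, seed = 17))
  pair <- sim$pair
  grid <- comparison_grid(pair, sim$truth$labels,
                          methods = c("or", "2dpca", "tcpca"),
                          classifiers = list(classifier_spec("knn")),
                          seed = 3, n_folds = 3, n_runs = 2, m = 2,
                          alpha_feature = 10, alpha_time = 10)
  expect_equal(nrow(grid$table), 3L * 1L * 3L)   # methods x classifiers x metrics
  expect_setequal(unique(grid$table$method), c("or", "2dpca", "tcpca"))
  # pairing contract: every entry holds the same (run, fold) index sets
  key <- function(e) paste(e$scores$run, e$scores$fold)
  keys <- vapply(grid$entries, function(e) paste(key(e), collapse = "|"), "")
  expect_equal(length(unique(keys)), 1L)
  # t-test columns populated for non-reference methods only
  acc <- grid$table[grid$table$metric == "acc", ]
  expect_true(all(is.na(acc$tcpca_significantly_better[acc$method == "tcpca"])))
  expect_true(all(!is.na(acc$tcpca_significantly_better[acc$method != "tcpca"])))
})
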