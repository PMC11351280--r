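test_that("read_cohort builds the tensor and mask from a long table", {
  df <- toy_long_table()
  grid <- visit_grid(c(0, 6))
  co <- read_cohort(df, grid = grid)
  expect_equal(dim(co$values), c(2, 2, 3))
  expect_true(all(co$mask))
  expect_equal(co$values["a", "m06", "x3"], 10)

  # deleting one subject-visit row masks exactly that slice
  co2 <- read_cohort(df[-2, ], grid = grid)
  expect_false(any(co2$mask["a", "m06", ]))
  expect_true(all(co2$mask["a", "m00", ]))
  expect_true(all(co2$mask["b", , ]))

  # row order is irrelevant
  shuffled <- df[c(3, 1, 4, 2), ]
  expect_identical(read_cohort(shuffled, grid = grid)$values, co$values)

  # an empty cell is masked but the rest of the row survives
  df_na <- df
  df_na$x2[1] <- NA
  co3 <- read_cohort(df_na, grid = grid)
  expect_false(co3$mask["a", "m00", "x2"])
  expect_true(co3$mask["a", "m00", "x1"])
})

test_that("read_cohort rejects malformed input", {
  df <- toy_long_table()
  grid <- visit_grid(c(0, 6))
  expect_error(read_cohort(rbind(df, df[1, ]), grid = grid),
               "duplicate \\(subject, visit\\) pair: \\(a, m00\\)")
  bad_visit <- df
  bad_visit$visit[1] <- "m99"
  expect_error(read_cohort(bad_visit, grid = grid), "unknown visit label")
  bad_type <- df
  bad_type$x1 <- as.character(bad_type$x1)
  expect_error(read_cohort(bad_type, grid = grid), "not numeric")
})

test_that("read_cohort round-trips through a CSV file", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(toy_long_table(), path)
  co <- read_cohort(path, grid = visit_grid(c(0, 6)))
  expect_equal(co$values["b", "m00", "x1"], 3)
})

test_that("align_time_grid reindexes, drops sparse subjects, and is idempotent", {
  grid8 <- default_visit_grid()
  withr::with_seed(1, {
    vals <- array(rnorm(4 * 8 * 3), c(4, 8, 3))
  })
  mask <- array(TRUE, dim(vals))
  mask[2, 4:8, ] <- FALSE          # subject 2 observed at 3 of 8 visits
  co <- longitudinal_cohort(vals, mask, paste0("s", 1:4), grid8, c("a", "b", "c"))

  # identity on an already aligned cohort
  same <- align_time_grid(co, grid8, min_fraction = 0)
  expect_equal(same$values, co$values)
  expect_equal(dim(same$values)[2], 8)

  # retention rule at the default threshold
  expect_message(dropped <- align_time_grid(co, grid8, min_fraction = 0.5),
                 "dropped 1 subject")
  expect_identical(attr(dropped, "dropped"), "s2")
  expect_equal(dropped$subject_ids, c("s1", "s3", "s4"))

  # idempotent
  again <- align_time_grid(dropped, grid8, min_fraction = 0.5)
  expect_equal(again$values, dropped$values)
  expect_equal(again$mask, dropped$mask)

  # subsetting to a narrower grid drops outside visits, missing slots masked
  grid_sub <- visit_grid(c(0, 6, 99))
  sub <- align_time_grid(co, grid_sub, min_fraction = 0)
  expect_equal(dim(sub$values)[2], 3)
  expect_false(any(sub$mask[, 3, ]))
  expect_equal(sub$values[, 1:2, ], co$values[, 1:2, ])

  expect_error(align_time_grid(co, grid8[0, ], min_fraction = 0), "empty")
  mask_all <- array(FALSE, dim(vals))
  co_empty <- longitudinal_cohort(vals, mask_all, paste0("s", 1:4), grid8,
                                  c("a", "b", "c"))
  expect_error(align_time_grid(co_empty, grid8), "all subjects dropped")
})

test_that("impute_missing fills by nearest subjects and respects observed cells", {
  # identity when nothing is missing
  co_full <- cohort_from_array(array(1:24, c(2, 3, 4)))
  expect_identical(impute_missing(co_full), co_full)

  # forced by definition: twin subject supplies the value with n_neighbors = 1
  vals <- array(rnorm(4 * 2 * 3), c(4, 2, 3))
  vals[2, , ] <- vals[1, , ]                 # b identical to a
  mask <- array(TRUE, dim(vals))
  mask[1, 2, 3] <- FALSE
  co <- cohort_from_array(vals, mask)
  imp <- impute_missing(co, n_neighbors = 1)
  expect_true(all(imp$mask))
  expect_equal(imp$values[1, 2, 3], vals[2, 2, 3])
  observed <- which(mask)
  expect_equal(imp$values[observed], vals[observed])

  # a cell observed in no subject is an error naming the cell
  mask_bad <- array(TRUE, dim(vals))
  mask_bad[, 1, 2] <- FALSE
  expect_error(impute_missing(cohort_from_array(vals, mask_bad)),
               "visit m00, feature f02")
})

test_that("knn imputation beats global mean filling on low-rank data", {
  withr::with_seed(7, {
    n <- 40; p <- 4; k <- 8
    u <- rnorm(k); g <- rnorm(p); z <- rnorm(n)
    vals <- outer(z, g %o% u) + array(rnorm(n * p * k, sd = 0.05), c(n, p, k))
    mask <- array(runif(n * p * k) > 0.1, c(n, p, k))
    co <- cohort_from_array(vals, mask)
    imp <- impute_missing(co, n_neighbors = 3)
    # mean-fill oracle
    vals_na <- vals; vals_na[!mask] <- NA
    cell_mean <- apply(vals_na, c(2, 3), mean, na.rm = TRUE)
    mean_fill <- vals
    for (t in seq_len(p)) for (f in seq_len(k)) {
      mean_fill[!mask[, t, f], t, f] <- cell_mean[t, f]
    }
    miss <- which(!mask)
    rmse_knn <- sqrt(mean((imp$values[miss] - vals[miss])^2))
    rmse_mean <- sqrt(mean((mean_fill[miss] - vals[miss])^2))
    expect_lt(rmse_knn, rmse_mean)
  })
})

test_that("locf imputation carries observations forward then backward", {
  vals <- array(0, c(2, 4, 1))
  vals[1, , 1] <- c(10, 0, 0, 40)
  vals[2, , 1] <- c(1, 2, 3, 4)
  mask <- array(TRUE, dim(vals))
  mask[1, 2:3, 1] <- FALSE
  co <- cohort_from_array(vals, mask)
  imp <- impute_missing(co, method = "locf")
  expect_equal(imp$values[1, , 1], c(10, 10, 10, 40), ignore_attr = TRUE)
})

test_that("standardization is pooled, flags degenerate cells, and round-trips", {
  pair <- toy_pair(n1 = 7, n2 = 5, p = 3, k = 4, seed = 11)
  expect_warning(std <- standardize_cohorts(pair), NA)
  pooled <- array(0, c(12, 3, 4))
  pooled[1:7, , ] <- std$target$values
  pooled[8:12, , ] <- std$background$values
  expect_lt(max(abs(apply(pooled, c(2, 3), mean))), 1e-10)
  expect_lt(max(abs(apply(pooled, c(2, 3), sd) - 1)), 1e-10)

  # stored scaling reproduces the standardized training data exactly
  again <- apply_scaling(pair$target, std$scaling)
  expect_identical(again$values, std$target$values)

  # constant feature -> zeros and a flag
  pair2 <- toy_pair(seed = 12)
  pair2$target$values[, , 2] <- 3
  pair2$background$values[, , 2] <- 3
  expect_warning(std2 <- standardize_cohorts(pair2), "zero-variance")
  expect_true(all(std2$target$values[, , 2] == 0))
  expect_true(all(std2$scaling$degenerate[, 2]))
})

test_that("the load-align-impute-standardize pipeline is deterministic", {
  run <- function() {
    df <- toy_long_table()
    df$x1[2] <- NA
    co <- read_cohort(df, grid = visit_grid(c(0, 6)))
    co <- align_time_grid(co, visit_grid(c(0, 6)), min_fraction = 0.5)
    co <- impute_missing(co, n_neighbors = 1)
    bg <- cohort_from_array(array(seq_len(12) / 7, c(2, 2, 3)),
                            ids = c("ba", "bb"))
    bg$feature_names <- co$feature_names
    dimnames(bg$values)[[3]] <- co$feature_names
    bg <- longitudinal_cohort(bg$values, bg$mask, bg$subject_ids,
                              bg$visit_grid, co$feature_names)
    standardize_cohorts(cohort_pair(co, bg))
  }
  expect_identical(run()$target$values, run()$target$values)
})
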