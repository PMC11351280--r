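test_that("contrastive covariance matches the explicit summation oracle", {
  withr::with_seed(3, {
    t_vals <- array(sample(-3:3, 3 * 2 * 2, replace = TRUE), c(3, 2, 2))
    b_vals <- array(sample(-3:3, 4 * 2 * 2, replace = TRUE), c(4, 2, 2))
  })
  pair <- cohort_pair(cohort_from_array(t_vals, ids = c("t1", "t2", "t3")),
                      cohort_from_array(b_vals, ids = paste0("b", 1:4)))
  for (axis in c("feature", "time")) {
    cc <- contrastive_covariance(pair, axis, alpha = 0.7)
    expect_equal(unname(cc$c_target), loop_axis_covariance(t_vals, axis),
                 tolerance = 1e-12)
    expect_equal(unname(cc$c_background), loop_axis_covariance(b_vals, axis),
                 tolerance = 1e-12)
    expect_equal(cc$combined, cc$c_target - 0.7 * cc$c_background,
                 tolerance = 1e-12)
    expect_lt(max(abs(cc$combined - t(cc$combined))), 1e-10)
  }
})

test_that("alpha = 0 gives the target covariance; identical cohorts cancel at alpha = 1", {
  pair <- toy_pair(seed = 5)
  cc0 <- contrastive_covariance(pair, "feature", alpha = 0)
  expect_identical(cc0$combined, cc0$c_target)

  twin <- cohort_pair(pair$target,
                      longitudinal_cohort(pair$target$values, NULL,
                                          paste0("bg", seq_len(dim(pair$target$values)[1])),
                                          pair$target$visit_grid,
                                          pair$target$feature_names))
  cc1 <- contrastive_covariance(twin, "time", alpha = 1)
  expect_lt(max(abs(cc1$combined)), 1e-12)
})

test_that("covariance requires N >= 2", {
  pair <- toy_pair(seed = 5)
  solo <- longitudinal_cohort(pair$target$values[1, , , drop = FALSE], NULL,
                              "only", pair$target$visit_grid,
                              pair$target$feature_names)
  expect_error(contrastive_covariance(cohort_pair(solo, pair$background),
                                      "feature", 1),
               "N >= 2")
})

test_that("top_contrastive_directions matches a dense eigensolver with fixed conventions", {
  mk_cov <- function(m) {
    structure(list(axis = "feature", c_target = m,
                   c_background = matrix(0, nrow(m), ncol(m)),
                   alpha = 0, combined = m),
              class = "contrastive_covariance")
  }
  # degenerate spectrum
  td <- top_contrastive_directions(mk_cov(diag(3)), 2)
  expect_equal(td$values, c(1, 1))
  expect_equal(crossprod(td$vectors), diag(2), tolerance = 1e-12)

  # diagonal with a negative eigenvalue
  td2 <- top_contrastive_directions(mk_cov(diag(c(3, 1, -2))), 2)
  expect_equal(td2$values, c(3, 1))
  expect_equal(abs(td2$vectors), cbind(c(1, 0, 0), c(0, 1, 0)), tolerance = 1e-12)
  expect_true(all(apply(td2$vectors, 2, max) > 0))  # sign convention

  # random symmetric 6x6 against the dense solver
  withr::with_seed(10, {
    a <- matrix(rnorm(36), 6); a <- (a + t(a)) / 2
  })
  td3 <- top_contrastive_directions(mk_cov(a), 6)
  rot <- crossprod(td3$vectors, a %*% td3$vectors)
  expect_lt(max(abs(rot - diag(td3$values))), 1e-9)
  expect_true(all(diff(td3$values) <= 1e-12))
  oracle <- eigen(a, symmetric = TRUE)
  expect_equal(abs(td3$vectors), abs(oracle$vectors), tolerance = 1e-8)
  expect_error(top_contrastive_directions(mk_cov(diag(3)), 4), "exceeds")
})

test_that("alpha = 0 T-cPCA equals two-sided PCA of the target cohort", {
  pair <- toy_pair(n1 = 12, n2 = 6, p = 4, k = 5, seed = 21)
  fit <- fit_tcpca(pair, alpha_feature = 0, alpha_time = 0,
                   m_feature = 3, m_time = 2)
  pca_f <- eigen(loop_axis_covariance(pair$target$values, "feature"), symmetric = TRUE)
  pca_t <- eigen(loop_axis_covariance(pair$target$values, "time"), symmetric = TRUE)
  expect_lt(max(principal_angles(fit$basis_feature,
                                 pca_f$vectors[, 1:3])), 1e-6)
  expect_lt(max(principal_angles(fit$basis_time,
                                 pca_t$vectors[, 1:2])), 1e-6)
})

test_that("p = 1 reduces the feature side to plain contrastive PCA on matrix data", {
  withr::with_seed(31, {
    t_vals <- array(rnorm(10 * 1 * 5), c(10, 1, 5))
    b_vals <- array(rnorm(8 * 1 * 5), c(8, 1, 5))
  })
  pair <- cohort_pair(cohort_from_array(t_vals, ids = paste0("t", 1:10)),
                      cohort_from_array(b_vals, ids = paste0("b", 1:8)))
  alpha <- 2.5
  fit <- fit_tcpca(pair, alpha_feature = alpha, alpha_time = 0,
                   m_feature = 2, m_time = 1)
  # oracle: cPCA on the N x k matrices directly (population covariance)
  cov_mat <- function(x) crossprod(scale(x, scale = FALSE)) / nrow(x)
  contrast <- cov_mat(t_vals[, 1, ]) - alpha * cov_mat(b_vals[, 1, ])
  oracle <- eigen((contrast + t(contrast)) / 2, symmetric = TRUE)
  expect_equal(abs(unname(fit$basis_feature)), abs(oracle$vectors[, 1:2]),
               tolerance = 1e-8)
  expect_equal(dim(fit$basis_time), c(1L, 1L))
  expect_equal(abs(unname(fit$basis_time[1, 1])), 1)
})

test_that("the bilinear projection is exact, linear, and order-consistent", {
  pair <- toy_pair(n1 = 5, n2 = 4, p = 3, k = 4, seed = 8)
  fit <- fit_tcpca(pair, 0.5, 0.5, m_feature = 2, m_time = 2)

  # identity bases reproduce the input slices
  fit_id <- fit
  fit_id$basis_feature <- diag(4); fit_id$basis_time <- diag(3)
  fit_id$m_feature <- 4L; fit_id$m_time <- 3L
  rep_id <- predict(fit_id, pair$target)
  expect_equal(rep_id$projected, pair$target$values, tolerance = 1e-12,
               ignore_attr = TRUE)

  # m = 1 scalar equals the explicit double sum u' S v
  fit1 <- fit_tcpca(pair, 0.5, 0.5, m_feature = 1, m_time = 1)
  rep1 <- predict(fit1, pair$target)
  s1 <- pair$target$values[2, , ]
  manual <- 0
  for (t in 1:3) for (f in 1:4) {
    manual <- manual + fit1$basis_time[t, 1] * s1[t, f] * fit1$basis_feature[f, 1]
  }
  expect_equal(rep1$projected[2, 1, 1], unname(manual), tolerance = 1e-10)

  # bilinearity
  a <- 0.3; b <- -1.7
  mixed <- a * pair$target$values[1, , ] + b * pair$target$values[2, , ]
  co_mix <- longitudinal_cohort(array(mixed, c(1, 3, 4)), NULL, "mix",
                                pair$target$visit_grid, pair$target$feature_names)
  rep_all <- predict(fit, pair$target)
  rep_mix <- predict(fit, co_mix)
  expect_equal(rep_mix$projected[1, , ],
               a * rep_all$projected[1, , ] + b * rep_all$projected[2, , ],
               tolerance = 1e-10)

  # flattened view is the row-major unfolding
  expect_equal(rep_all$flat[3, ], as.vector(t(rep_all$projected[3, , ])),
               ignore_attr = TRUE)
})

test_that("full orthonormal bases preserve Frobenius norm", {
  pair <- toy_pair(n1 = 6, n2 = 6, p = 3, k = 4, seed = 9)
  fit <- fit_tcpca(pair, 1, 1, m_feature = 4, m_time = 3)
  rep <- predict(fit, pair$target)
  for (i in 1:6) {
    expect_equal(sqrt(sum(rep$projected[i, , ]^2)),
                 sqrt(sum(pair$target$values[i, , ]^2)), tolerance = 1e-10)
  }
})

test_that("select_ranks takes the minimal m covering the positive energy", {
  mk_cov <- function(vals) {
    m <- diag(vals)
    structure(list(axis = "feature", c_target = m, c_background = 0 * m,
                   alpha = 0, combined = m),
              class = "contrastive_covariance")
  }
  expect_equal(select_ranks(mk_cov(c(9, 1, -3)), energy = 0.9)$m_feature, 1L)
  expect_equal(select_ranks(mk_cov(c(5, 5)), energy = 0.99)$m_feature, 2L)
  expect_error(select_ranks(mk_cov(c(-1, -2)), energy = 0.5),
               "no positive contrastive eigenvalue")

  # random spectra against an exhaustive scan
  withr::with_seed(17, {
    for (rep in 1:20) {
      vals <- sort(rnorm(8, sd = 3), decreasing = TRUE)
      if (all(vals <= 0)) vals[1] <- 1
      energy <- runif(1, 0.1, 1)
      got <- select_ranks(mk_cov(vals), energy = energy)$m_feature
      pos <- vals[vals > 0]
      scan <- min(which(sapply(seq_along(pos),
                               function(m) sum(pos[1:m]) / sum(pos) >= energy - 1e-12)))
      expect_equal(got, max(1L, scan))
    }
  })
})

test_that("the fitted top direction maximizes the variance contrast", {
  pair <- toy_pair(n1 = 15, n2 = 12, p = 3, k = 6, seed = 23)
  alpha <- 1.5
  cc <- contrastive_covariance(pair, "feature", alpha)
  top <- top_contrastive_directions(cc, 1)
  v <- top$vectors[, 1]
  best <- drop(t(v) %*% cc$combined %*% v)
  withr::with_seed(24, {
    for (probe in 1:50) {
      u <- rnorm(6); u <- u / sqrt(sum(u^2))
      expect_lte(drop(t(u) %*% cc$combined %*% u), best + 1e-8)
    }
  })
})

test_that("background variance along the top direction shrinks as alpha grows", {
  sim <- generate_cohorts(synthetic_spec(n_target = 120, n_background = 80,
                                         k = 20, seed = 4))
  pair <- sim$pair
  cb <- contrastive_covariance(pair, "feature", 0)$c_background
  bg_var <- sapply(c(0, 1, 5, 20, 100), function(a) {
    v <- fit_tcpca(pair, a, 0, m_feature = 1, m_time = 1)$basis_feature[, 1]
    drop(t(v) %*% cb %*% v)
  })
  expect_true(all(diff(bg_var) <= 1e-8))
})
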