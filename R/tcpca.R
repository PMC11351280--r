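#' Contrastive covariance on one tensor axis
#'
#' For a cohort of p x k matrices S_i centered by the cohort mean matrix S-bar,
#' the feature-axis covariance is (1/N) * sum_i (S_i - S-bar)' (S_i - S-bar)
#' (k x k) and the time-axis covariance is (1/N) * sum_i
#' (S_i - S-bar) (S_i - S-bar)' (p x p). The combined matrix is
#' C_target - alpha * C_background, symmetrized as (C + C')/2 for numerical
#' safety; its leading eigenvectors are directions of variance enriched in the
#' target cohort relative to the background cohort.
#'
#' @param pair A fully observed (imputed) `cohort_pair`.
#' @param axis `"feature"` (k x k) or `"time"` (p x p).
#' @param alpha Nonnegative contrast strength.
#' @return An object of class `contrastive_covariance` with fields `axis`,
#'   `c_target`, `c_background`, `alpha`, `combined`.
#' @export
contrastive_covariance <- function(pair, axis = c("feature", "time"), alpha) {
  axis <- match.arg(axis)
  assert_that(inherits(pair, "cohort_pair"), "`pair` must be a cohort_pair")
  assert_that(is_number(alpha) && alpha >= 0, "`alpha` must be a nonnegative number")
  assert_that(all(pair$target$mask) && all(pair$background$mask),
              "cohorts must be imputed (fully observed)")
  ct <- axis_covariance(pair$target$values, axis)
  cb <- axis_covariance(pair$background$values, axis)
  assert_that(identical(dim(ct), dim(cb)), "axis shape mismatch between cohorts")
  combined <- ct - alpha * cb
  combined <- (combined + t(combined)) / 2
  nm <- if (axis == "feature") pair$target$feature_names else
    pair$target$visit_grid$label
  dimnames(combined) <- dimnames(ct) <- dimnames(cb) <- list(nm, nm)
  structure(list(axis = axis, c_target = ct, c_background = cb,
                 alpha = alpha, combined = combined),
            class = "contrastive_covariance")
}

# Per-cohort covariance of one axis; values is an N x p x k array.
axis_covariance <- function(values, axis) {
  d <- dim(values)
  assert_that(d[1] >= 2L, "a cohort needs N >= 2 subjects for a covariance")
  mean_mat <- apply(values, c(2, 3), mean)        # cohort mean tensor S-bar
  centered <- sweep(values, c(2, 3), mean_mat)
  if (axis == "feature") {
    stacked <- matrix(centered, nrow = d[1] * d[2], ncol = d[3])
    cc <- crossprod(stacked) / d[1]
  } else {
    stacked <- matrix(aperm(centered, c(1, 3, 2)), nrow = d[1] * d[3], ncol = d[2])
    cc <- crossprod(stacked) / d[1]
  }
  (cc + t(cc)) / 2
}

#' @export
print.contrastive_covariance <- function(x, ...) {
  cat(sprintf("<contrastive_covariance> axis = %s (%d x %d), alpha = %g\n",
              x$axis, nrow(x$combined), ncol(x$combined), x$alpha))
  invisible(x)
}

#' Leading directions of a contrastive covariance
#'
#' Returns the m eigenvectors of the (symmetric, generally indefinite)
#' combined matrix with algebraically largest eigenvalues. Columns are
#' orthonormal, eigenvalues non-increasing; each column's sign is fixed so
#' that its largest-magnitude entry is positive (ties broken by index), which
#' makes outputs reproducible across platforms.
#'
#' @param cov A `contrastive_covariance`.
#' @param m Number of directions, at most the matrix dimension.
#' @return List with `vectors` (d x m) and `values` (length m).
#' @export
top_contrastive_directions <- function(cov, m) {
  assert_that(inherits(cov, "contrastive_covariance"),
              "`cov` must be a contrastive_covariance")
  dmat <- nrow(cov$combined)
  assert_that(is_number(m) && m >= 1 && m == round(m), "`m` must be a positive integer")
  assert_that(m <= dmat, sprintf("m = %d exceeds the matrix dimension %d", m, dmat))
  eig <- eigen(cov$combined, symmetric = TRUE)
  vectors <- eig$vectors[, seq_len(m), drop = FALSE]
  vectors <- fix_signs(vectors)
  rownames(vectors) <- rownames(cov$combined)
  list(vectors = vectors, values = eig$values[seq_len(m)])
}

# Flip each column so its largest-|entry| (first such index on ties) is positive.
fix_signs <- function(v) {
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  v
}

#' Choose ranks from the positive contrastive spectrum
#'
#' The smallest m whose positive eigenvalues capture at least `energy` of the
#' total positive-eigenvalue mass, per axis; always at least 1.
#'
#' @param cov_feature,cov_time `contrastive_covariance` objects for the two
#'   axes (either may be `NULL` to skip that axis).
#' @param energy Fraction in (0, 1]; default 0.9.
#' @return Named list `m_feature`, `m_time` (NULL where the axis was skipped).
#' @export
select_ranks <- function(cov_feature = NULL, cov_time = NULL, energy = 0.9) {
  assert_that(is_number(energy) && energy > 0 && energy <= 1,
              "`energy` must lie in (0, 1]")
  pick <- function(cov) {
    if (is.null(cov)) return(NULL)
    vals <- eigen(cov$combined, symmetric = TRUE, only.values = TRUE)$values
    rank_from_spectrum(vals, energy)
  }
  list(m_feature = pick(cov_feature), m_time = pick(cov_time))
}

rank_from_spectrum <- function(vals, energy, strict = TRUE) {
  pos <- vals[vals > 0]
  if (length(pos) == 0) {
    # at large alpha the whole spectrum can be negative; the leading
    # (least-negative) direction is still the argmax of the contrast
    assert_that(!strict,
                "no positive contrastive eigenvalue: the cohorts are indistinguishable at this alpha")
    return(1L)
  }
  cum <- cumsum(pos) / sum(pos)
  max(1L, which(cum >= energy - 1e-12)[1L])
}

#' Fit tensorized contrastive PCA
#'
#' Fits contrastive bases on the feature axis (k x m_feature) and the time
#' axis (p x m_time) of a standardized, imputed cohort pair. With
#' `alpha_feature = alpha_time = 0` this reduces to ordinary two-sided PCA of
#' the target cohort. The ablations keep one axis untouched: mode
#' `"feature_only"` uses the p x p identity for time, `"time_only"` the k x k
#' identity for features.
#'
#' @param pair A `cohort_pair`, ideally from [standardize_cohorts()].
#' @param alpha_feature,alpha_time Nonnegative contrast strengths.
#' @param m_feature,m_time Ranks; `NULL` selects them by [select_ranks()] at
#'   `energy`.
#' @param energy Positive-eigenvalue energy fraction for automatic rank
#'   selection (default 0.9).
#' @param mode `"full"`, `"feature_only"` or `"time_only"`.
#' @return An object of class `tcpca_fit`.
#' @export
fit_tcpca <- function(pair, alpha_feature = 1, alpha_time = 1,
                      m_feature = NULL, m_time = NULL, energy = 0.9,
                      mode = c("full", "feature_only", "time_only")) {
  mode <- match.arg(mode)
  assert_that(inherits(pair, "cohort_pair"), "`pair` must be a cohort_pair")
  d <- dim(pair$target$values)
  p <- d[2]; k <- d[3]
  basis_feature <- diag(k); eig_feature <- rep(NA_real_, k)
  basis_time <- diag(p); eig_time <- rep(NA_real_, p)
  alpha_f_used <- alpha_feature; alpha_t_used <- alpha_time

  if (mode %in% c("full", "feature_only")) {
    cov_f <- contrastive_covariance(pair, "feature", alpha_feature)
    if (is.null(m_feature)) {
      m_feature <- rank_from_spectrum(
        eigen(cov_f$combined, symmetric = TRUE, only.values = TRUE)$values,
        energy, strict = FALSE)
    }
    assert_that(m_feature <= k, sprintf("m_feature = %d exceeds k = %d", m_feature, k))
    top_f <- top_contrastive_directions(cov_f, m_feature)
    basis_feature <- top_f$vectors; eig_feature <- top_f$values
  } else {
    m_feature <- k; alpha_f_used <- NA_real_
  }
  if (mode %in% c("full", "time_only")) {
    cov_t <- contrastive_covariance(pair, "time", alpha_time)
    if (is.null(m_time)) {
      m_time <- rank_from_spectrum(
        eigen(cov_t$combined, symmetric = TRUE, only.values = TRUE)$values,
        energy, strict = FALSE)
    }
    assert_that(m_time <= p, sprintf("m_time = %d exceeds p = %d", m_time, p))
    top_t <- top_contrastive_directions(cov_t, m_time)
    basis_time <- top_t$vectors; eig_time <- top_t$values
  } else {
    m_time <- p; alpha_t_used <- NA_real_
  }
  rownames(basis_feature) <- pair$target$feature_names
  rownames(basis_time) <- pair$target$visit_grid$label
  structure(
    list(basis_feature = basis_feature, basis_time = basis_time,
         eigvals_feature = eig_feature, eigvals_time = eig_time,
         alpha_feature = alpha_f_used, alpha_time = alpha_t_used,
         m_feature = ncol(basis_feature), m_time = ncol(basis_time),
         mode = mode,
         centering = list(
           target = apply(pair$target$values, c(2, 3), mean),
           background = apply(pair$background$values, c(2, 3), mean)),
         scaling = pair$scaling,
         feature_names = pair$target$feature_names,
         visit_grid = pair$target$visit_grid),
    class = "tcpca_fit")
}

#' @export
print.tcpca_fit <- function(x, ...) {
  cat(sprintf("<tcpca_fit> mode = %s\n", x$mode))
  cat(sprintf("  feature basis: %d x %d (alpha = %s)\n",
              nrow(x$basis_feature), x$m_feature, format(x$alpha_feature)))
  cat(sprintf("  time basis:    %d x %d (alpha = %s)\n",
              nrow(x$basis_time), x$m_time, format(x$alpha_time)))
  invisible(x)
}

#' Project a cohort through a fitted T-cPCA basis
#'
#' Applies the bilinear map S_i -> M_time' S_i M_feature to every subject.
#' If the fit carries a scaling record and the cohort is not already
#' standardized, the stored scaling is applied first so held-out subjects are
#' transformed identically to the training cohorts.
#'
#' @param object A `tcpca_fit`.
#' @param cohort A fully observed `longitudinal_cohort` with matching visits
#'   and features.
#' @param ... Unused.
#' @return An object of class `tcpca_representation` holding the per-subject
#'   m_time x m_feature matrices and their row-major flattened N x
#'   (m_time * m_feature) view.
#' @export
predict.tcpca_fit <- function(object, cohort, ...) {
  assert_that(inherits(cohort, "longitudinal_cohort"),
              "`cohort` must be a longitudinal_cohort")
  assert_that(all(cohort$mask), "cohort must be fully observed")
  assert_that(identical(cohort$feature_names, object$feature_names) &&
                identical(cohort$visit_grid$label, object$visit_grid$label),
              "cohort shape does not match the fitted basis")
  if (!is.null(object$scaling) && !isTRUE(attr(cohort, "standardized"))) {
    cohort <- apply_scaling(cohort, object$scaling)
  }
  d <- dim(cohort$values)
  mt <- object$m_time; mf <- object$m_feature
  projected <- array(0, dim = c(d[1], mt, mf))
  for (i in seq_len(d[1])) {
    s_i <- matrix(cohort$values[i, , ], nrow = d[2], ncol = d[3])
    projected[i, , ] <- crossprod(object$basis_time, s_i %*% object$basis_feature)
  }
  flat <- flatten_rowmajor(projected,
                           visit_labels = paste0("t", seq_len(mt)),
                           feature_names = paste0("f", seq_len(mf)))
  rownames(flat) <- cohort$subject_ids
  structure(list(projected = projected, flat = flat,
                 subject_ids = cohort$subject_ids,
                 m_time = mt, m_feature = mf, mode = object$mode),
            class = "tcpca_representation")
}

#' @export
print.tcpca_representation <- function(x, ...) {
  cat(sprintf("<tcpca_representation> %d subjects, %d x %d (time x feature), flat d = %d\n",
              length(x$subject_ids), x$m_time, x$m_feature, ncol(x$flat)))
  invisible(x)
}

#' @rdname predict.tcpca_fit
#' @param basis A `tcpca_fit`.
#' @export
transform_cohort <- function(basis, cohort) predict(basis, cohort)

#' Tidy a T-cPCA fit
#'
#' One row per (axis, component) with its eigenvalue; `glance()` returns a
#' one-row summary.
#' @param x A `tcpca_fit`.
#' @param ... Unused.
#' @export
tidy.tcpca_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(axis = "feature", component = seq_len(x$m_feature),
                   eigenvalue = x$eigvals_feature[seq_len(x$m_feature)]),
    tibble::tibble(axis = "time", component = seq_len(x$m_time),
                   eigenvalue = x$eigvals_time[seq_len(x$m_time)])
  )
}

#' @rdname tidy.tcpca_fit
#' @export
glance.tcpca_fit <- function(x, ...) {
  tibble::tibble(mode = x$mode, m_feature = x$m_feature, m_time = x$m_time,
                 alpha_feature = x$alpha_feature, alpha_time = x$alpha_time,
                 n_features = nrow(x$basis_feature), n_visits = nrow(x$basis_time))
}

#' Spectrum plot for a T-cPCA fit
#'
#' Bar plot of the retained contrastive eigenvalues per axis.
#' @param object A `tcpca_fit`.
#' @param ... Unused.
#' @export
autoplot.tcpca_fit <- function(object, ...) {
  df <- tidy.tcpca_fit(object)
  df <- df[is.finite(df$eigenvalue), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$eigenvalue)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~axis, scales = "free") +
    ggplot2::labs(x = "component", y = "contrastive eigenvalue",
                  title = "T-cPCA contrastive spectra") +
    ggplot2::theme_minimal()
}
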