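#' Feature tables
#'
#' All representation methods return a `feature_table`: a tibble with a
#' `subject_id` column followed by numeric columns, one row per subject in
#' cohort order, carrying a `provenance` attribute naming the method
#' (OR, SOR, 2DPCA, PCA1..PCA5, TcPCA0, TcPCA1, TcPCA).
#'
#' @param mat Numeric matrix N x d with column names.
#' @param subject_ids N subject identifiers.
#' @param provenance Method tag.
#' @return A `feature_table` tibble.
#' @export
feature_table <- function(mat, subject_ids, provenance) {
  assert_that(is.matrix(mat) && all(is.finite(mat)),
              "a feature table must be a finite numeric matrix")
  assert_that(nrow(mat) == length(subject_ids),
              "one row per subject required")
  if (is.null(colnames(mat))) colnames(mat) <- paste0("x", seq_len(ncol(mat)))
  out <- tibble::as_tibble(as.data.frame(mat, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(subject_id = as.character(subject_ids)), out)
  attr(out, "provenance") <- provenance
  class(out) <- c("feature_table", class(out))
  out
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> provenance = %s, %d subjects x %d columns\n",
              attr(x, "provenance") %||% "?", nrow(x), ncol(x) - 1L))
  NextMethod()
}

# Numeric matrix view (drops subject_id).
ft_matrix <- function(table) {
  if (inherits(table, "feature_table") || (is.data.frame(table) &&
                                           "subject_id" %in% names(table))) {
    m <- as.matrix(table[setdiff(names(table), "subject_id")])
    rownames(m) <- table$subject_id
    m
  } else {
    as.matrix(table)
  }
}

#' Raw flattening representation (OR)
#'
#' Flattens each subject's p x k matrix row-major (visit-major) into a
#' length p*k vector.
#' @param cohort A fully observed `longitudinal_cohort`.
#' @return A `feature_table` with d = p*k columns.
#' @export
represent_or <- function(cohort) {
  assert_that(all(cohort$mask), "cohort must be imputed before representation")
  flat <- flatten_rowmajor(cohort$values, cohort$visit_grid$label,
                           cohort$feature_names)
  feature_table(flat, cohort$subject_ids, "OR")
}

#' Time-series summary representation (SOR)
#'
#' For each feature, seven statistics of its time series: mean, standard
#' deviation, maximum, minimum, variance, skewness and kurtosis. Variance and
#' standard deviation are population moments; skewness is Fisher's g1 and
#' kurtosis is excess kurtosis (g2), both defined as 0 for zero-variance
#' series. Columns are statistic-major: all means first, then all sds, and so
#' on (`mean.<feature>`, ..., `kurtosis.<feature>`).
#'
#' @param cohort A fully observed `longitudinal_cohort` with p >= 2 visits.
#' @return A `feature_table` with d = 7k columns.
#' @export
represent_sor <- function(cohort) {
  assert_that(all(cohort$mask), "cohort must be imputed before representation")
  d <- dim(cohort$values)
  assert_that(d[2] >= 2L, "SOR needs at least 2 visits (p >= 2)")
  stats_fun <- function(v) {
    m <- mean(v)
    cv <- v - m
    m2 <- mean(cv^2)
    if (m2 < .Machine$double.eps) {
      c(m, 0, max(v), min(v), 0, 0, 0)
    } else {
      c(m, sqrt(m2), max(v), min(v), m2,
        mean(cv^3) / m2^1.5, mean(cv^4) / m2^2 - 3)
    }
  }
  stat_names <- c("mean", "sd", "max", "min", "var", "skewness", "kurtosis")
  out <- matrix(0, nrow = d[1], ncol = 7L * d[3])
  for (i in seq_len(d[1])) {
    s <- apply(matrix(cohort$values[i, , ], nrow = d[2], ncol = d[3]),
               2, stats_fun)                     # 7 x k
    out[i, ] <- as.vector(t(s))                  # statistic-major
  }
  colnames(out) <- as.vector(outer(cohort$feature_names, stat_names,
                                   function(f, s) paste(s, f, sep = ".")))
  feature_table(out, cohort$subject_ids, "SOR")
}

#' Two-dimensional PCA representation (2DPCA)
#'
#' Feature-axis covariance of the target cohort only (no background
#' subtraction); each subject is mapped to S_i M with the top-m eigenvectors
#' and flattened, d = p*m. Definitionally equal to the feature-only T-cPCA
#' ablation at alpha = 0.
#'
#' @param pair A `cohort_pair` (only the target cohort is used for the basis).
#' @param m Number of feature-axis components.
#' @return A `feature_table` with d = p*m columns.
#' @export
represent_2dpca <- function(pair, m) {
  d <- dim(pair$target$values)
  assert_that(m <= d[3], sprintf("m = %d exceeds k = %d", m, d[3]))
  fit <- fit_tcpca(pair, alpha_feature = 0, m_feature = m,
                   mode = "feature_only")
  rep <- predict(fit, pair$target)
  out <- rep$flat
  colnames(out) <- as.vector(t(outer(pair$target$visit_grid$label,
                                     paste0("pc", seq_len(m)), paste, sep = ".")))
  feature_table(out, pair$target$subject_ids, "2DPCA")
}

#' Kernel PCA representation
#'
#' Standard kernel PCA on the double-centered Gram matrix of the flattened
#' (OR) subject vectors: scores are eigenvectors scaled by the square root of
#' their eigenvalues. Components with nonpositive eigenvalues (possible for
#' the indefinite sigmoid kernel) are dropped with a warning.
#'
#' Default kernel parameters: `gamma = 1/d` (rbf, polynomial, sigmoid),
#' polynomial `degree = 3` and `coef0 = 1`, sigmoid `coef0 = 1`, rational
#' quadratic `alpha = 1` with length scale equal to the median pairwise
#' distance.
#'
#' @param cohort A fully observed `longitudinal_cohort`.
#' @param kernel One of `"rbf"`, `"rational_quadratic"`, `"linear"`,
#'   `"polynomial"`, `"sigmoid"`.
#' @param m Number of components, less than N.
#' @param kernel_params Named list overriding defaults (`gamma`, `degree`,
#'   `coef0`, `alpha`, `length_scale`).
#' @return A `feature_table` with up to m columns (tag PCA1..PCA5 by kernel).
#' @export
represent_kernel_pca <- function(cohort,
                                 kernel = c("rbf", "rational_quadratic",
                                            "linear", "polynomial", "sigmoid"),
                                 m, kernel_params = list()) {
  kernel <- match.arg(kernel)
  assert_that(all(cohort$mask), "cohort must be imputed before representation")
  x <- flatten_rowmajor(cohort$values)
  n <- nrow(x); d <- ncol(x)
  assert_that(m < n, "kernel PCA needs m < N")
  km <- kernel_matrix(x, kernel, kernel_params)
  # double centering: K' = K - 1K/n - K1/n + 1K1/n^2
  kc <- sweep(sweep(km, 1, rowMeans(km)), 2, colMeans(km)) + mean(km)
  kc <- (kc + t(kc)) / 2
  eig <- eigen(kc, symmetric = TRUE)
  keep <- seq_len(m)
  pos <- eig$values[keep] > n * .Machine$double.eps * max(abs(eig$values))
  if (!all(pos)) {
    rlang::warn(sprintf(
      "kernel PCA (%s): dropped %d component(s) with nonpositive eigenvalues",
      kernel, sum(!pos)))
    keep <- keep[pos]
  }
  scores <- sweep(eig$vectors[, keep, drop = FALSE], 2,
                  sqrt(eig$values[keep]), "*")
  scores <- fix_signs(scores)
  colnames(scores) <- paste0("kpc", keep)
  tag <- c(rbf = "PCA1", rational_quadratic = "PCA2", linear = "PCA3",
           polynomial = "PCA4", sigmoid = "PCA5")[[kernel]]
  feature_table(scores, cohort$subject_ids, tag)
}

kernel_matrix <- function(x, kernel, params) {
  n <- nrow(x); d <- ncol(x)
  gamma <- params$gamma %||% (1 / d)
  if (kernel %in% c("rbf", "rational_quadratic")) {
    sq <- rowSums(x^2)
    d2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(x), 0)
  }
  switch(kernel,
    linear = tcrossprod(x),
    rbf = exp(-gamma * d2),
    polynomial = (gamma * tcrossprod(x) + (params$coef0 %||% 1)) ^
      (params$degree %||% 3),
    sigmoid = tanh(gamma * tcrossprod(x) + (params$coef0 %||% 1)),
    rational_quadratic = {
      a <- params$alpha %||% 1
      ls <- params$length_scale %||% stats::median(sqrt(d2[upper.tri(d2)]))
      if (!is.finite(ls) || ls <= 0) ls <- 1
      (1 + d2 / (2 * a * ls^2)) ^ (-a)
    })
}

#' All comparator representations by name
#'
#' Dispatch helper used by the evaluation grid: builds the representation of
#' the target cohort for any method tag.
#'
#' @param pair A standardized `cohort_pair`.
#' @param method One of `"or"`, `"sor"`, `"2dpca"`, `"pca1"`..`"pca5"`,
#'   `"tcpca0"` (feature-only ablation), `"tcpca1"` (time-only ablation),
#'   `"tcpca"`.
#' @param m Component count for the subspace methods (default 5).
#' @param alpha_feature,alpha_time Contrast strengths for the T-cPCA variants.
#' @return A `feature_table` for the target cohort.
#' @export
represent <- function(pair, method, m = 5, alpha_feature = 1, alpha_time = 1) {
  method <- match.arg(tolower(method),
                      c("or", "sor", "2dpca", paste0("pca", 1:5),
                        "tcpca0", "tcpca1", "tcpca"))
  kern <- c(pca1 = "rbf", pca2 = "rational_quadratic", pca3 = "linear",
            pca4 = "polynomial", pca5 = "sigmoid")
  if (method == "or") return(represent_or(pair$target))
  if (method == "sor") return(represent_sor(pair$target))
  if (method == "2dpca") return(represent_2dpca(pair, m = m))
  if (method %in% names(kern)) {
    return(represent_kernel_pca(pair$target, kern[[method]], m = m))
  }
  mode <- switch(method, tcpca0 = "feature_only", tcpca1 = "time_only",
                 tcpca = "full")
  fit <- fit_tcpca(pair, alpha_feature = alpha_feature, alpha_time = alpha_time,
                   mode = mode)
  rep <- predict(fit, pair$target)
  tag <- switch(method, tcpca0 = "TcPCA0", tcpca1 = "TcPCA1", tcpca = "TcPCA")
  feature_table(rep$flat, pair$target$subject_ids, tag)
}
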