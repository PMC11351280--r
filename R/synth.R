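#' Specification of a synthetic longitudinal cohort pair
#'
#' The generator emulates the statistical structure the contrastive model
#' assumes: both cohorts share a dominant low-rank "aging" component (smooth
#' monotone time trend on orthonormal feature directions), the target cohort
#' additionally carries a "disease" component on feature directions
#' orthogonal to aging with a late-onset ramp time profile, subject disease
#' scores cluster into planted subtypes, three-class progression labels are
#' linked to the disease scores, and cells may be masked missing at random.
#' Per-cell variance decomposes into `sigma2_age + sigma2_dis + noise`, with
#' the component scores standardized so the shares hold exactly in sample.
#'
#' @param n_target,n_background Cohort sizes (defaults 400 / 200).
#' @param p,k Visits and features (defaults 8 / 60).
#' @param n_aging_axes,n_disease_axes Numbers of planted axes (defaults 1/1).
#' @param sigma2_age,sigma2_dis Variance shares of the aging and disease
#'   components (defaults 0.6 / 0.15); the white-noise share is the
#'   remainder.
#' @param n_subtypes Planted subtype count (default 4).
#' @param subtype_separation Centroid spacing in units of within-subtype SD
#'   (default 10).
#' @param label_proportions Named proportions for classes `-1`, `0`, `1`
#'   (default the 1-year mix 198:1644:67).
#' @param label_slope Coupling of the latent label score to the disease score
#'   relative to the logistic noise (default 3).
#' @param missing_rate Fraction of cells masked unobserved (default 0).
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_target = 400, n_background = 200, p = 8, k = 60,
                           n_aging_axes = 1, n_disease_axes = 1,
                           sigma2_age = 0.6, sigma2_dis = 0.15,
                           n_subtypes = 4, subtype_separation = 10,
                           label_proportions = c(`-1` = 198, `0` = 1644, `1` = 67),
                           label_slope = 3, missing_rate = 0, seed = 1) {
  assert_that(sigma2_age > 0 && sigma2_dis > 0 &&
                sigma2_age + sigma2_dis < 1,
              "variance shares must be positive with sigma2_age + sigma2_dis < 1")
  assert_that(n_aging_axes + n_disease_axes <= k,
              "more planted axes than features")
  assert_that(missing_rate >= 0 && missing_rate < 1,
              "`missing_rate` must lie in [0, 1)")
  lp <- label_proportions / sum(label_proportions)
  assert_that(all(c("-1", "0", "1") %in% names(lp)),
              "`label_proportions` must be named -1, 0, 1")
  structure(list(n_target = n_target, n_background = n_background, p = p,
                 k = k, n_aging_axes = n_aging_axes,
                 n_disease_axes = n_disease_axes, sigma2_age = sigma2_age,
                 sigma2_dis = sigma2_dis, n_subtypes = n_subtypes,
                 subtype_separation = subtype_separation,
                 label_proportions = lp[c("-1", "0", "1")],
                 label_slope = label_slope, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Study-scale synthetic specification
#'
#' The study-scale layout: 8 semiannual visits, 1909 target and 884
#' background subjects, 1-year label mix 67 better : 198 worse : 1644
#' unchanged. The feature count defaults to a desk-scale 60 (872 is the
#' full-scale value and remains available via `k`).
#'
#' @param k Feature count (default 60).
#' @param ... Overrides passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
default_study_scale_spec <- function(k = 60, ...) {
  synthetic_spec(n_target = 1909, n_background = 884, p = 8, k = k,
                 label_proportions = c(`-1` = 198, `0` = 1644, `1` = 67), ...)
}

# Unit-norm smooth monotone time profile (aging) per axis: powers of a ramp.
aging_profiles <- function(p, n_axes) {
  t <- seq_len(p) / p
  sapply(seq_len(n_axes), function(a) {
    g <- t ^ (0.5 + 0.5 * (a - 1))
    g / sqrt(sum(g^2))
  })
}

# Unit-norm late-onset ramp (disease): flat until mid-span, then rising.
disease_profiles <- function(p, n_axes) {
  t <- seq_len(p)
  onset <- ceiling(p / 2)
  sapply(seq_len(n_axes), function(a) {
    h <- pmax(0, t - onset + (a - 1))
    if (all(h == 0)) h[p] <- 1
    h / sqrt(sum(h^2))
  })
}

# Center and rescale columns to an exact sample variance.
scale_to_var <- function(z, target_var) {
  z <- scale(z)
  sweep(z, 2, sqrt(target_var), "*")
}

#' Generate a synthetic cohort pair with known ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `synthetic_cohorts`: `$pair` (an unstandardized
#'   `cohort_pair`), `$truth` (progression labels, subtype assignments,
#'   planted feature axes and time profiles, subject scores).
#' @export
generate_cohorts <- function(spec) {
  assert_that(inherits(spec, "synthetic_spec"), "`spec` must be a synthetic_spec")
  with_local_seed(spec$seed, {
    p <- spec$p; k <- spec$k
    ra <- spec$n_aging_axes; rd <- spec$n_disease_axes
    n1 <- spec$n_target; n2 <- spec$n_background
    q <- qr.Q(qr(matrix(stats::rnorm(k * (ra + rd)), nrow = k)))
    u_age <- q[, seq_len(ra), drop = FALSE]
    u_dis <- q[, ra + seq_len(rd), drop = FALSE]
    g_age <- aging_profiles(p, ra)
    g_dis <- disease_profiles(p, rd)

    cell_var_age <- spec$sigma2_age / ra
    cell_var_dis <- spec$sigma2_dis / rd
    # one measurement-noise level for both cohorts (instrument noise does not
    # depend on diagnosis); target cells have unit total variance
    noise_sd <- sqrt(1 - spec$sigma2_age - spec$sigma2_dis)

    # aging scores (both cohorts): per-cell variance share sigma2_age after
    # averaging |g|^2 |u|^2 = 1/(p k) over cells
    z_age_t <- scale_to_var(matrix(stats::rnorm(n1 * ra), n1, ra),
                            p * k * cell_var_age)
    z_age_b <- scale_to_var(matrix(stats::rnorm(n2 * ra), n2, ra),
                            p * k * cell_var_age)

    # disease scores (target only): subtype centroids + within-subtype spread,
    # standardized afterwards so the share includes the subtype structure
    subtype <- sort(rep_len(seq_len(spec$n_subtypes), n1))
    # unit within-subtype SD, so `subtype_separation` is the centroid spacing
    # in sigma units: collinear equispaced centroids when rd = 1, otherwise
    # random centroids rescaled to unit minimum pairwise distance
    if (rd == 1) {
      centroids <- matrix(seq_len(spec$n_subtypes) - (spec$n_subtypes + 1) / 2,
                          ncol = 1)
    } else {
      centroids <- matrix(stats::rnorm(spec$n_subtypes * rd),
                          spec$n_subtypes, rd)
      centroids <- centroids / max(min(stats::dist(centroids)), 1e-12)
    }
    z_dis_raw <- centroids[subtype, , drop = FALSE] * spec$subtype_separation +
      matrix(stats::rnorm(n1 * rd), n1, rd)
    z_dis <- scale_to_var(z_dis_raw, p * k * cell_var_dis)

    build <- function(z_age, z_dis_mat, noise_sd, n) {
      values <- array(stats::rnorm(n * p * k, sd = noise_sd), dim = c(n, p, k))
      for (a in seq_len(ra)) {
        values <- values + outer(z_age[, a], g_age[, a] %o% u_age[, a])
      }
      if (!is.null(z_dis_mat)) {
        for (b in seq_len(rd)) {
          values <- values + outer(z_dis_mat[, b], g_dis[, b] %o% u_dis[, b])
        }
      }
      values
    }
    target_values <- build(z_age_t, z_dis, noise_sd, n1)
    background_values <- build(z_age_b, NULL, noise_sd, n2)

    grid <- visit_grid(seq(0, by = 6, length.out = p))
    target_ids <- sprintf("T%04d", seq_len(n1))
    background_ids <- sprintf("B%04d", seq_len(n2))

    mask_t <- array(stats::runif(n1 * p * k) >= spec$missing_rate, c(n1, p, k))
    mask_b <- array(stats::runif(n2 * p * k) >= spec$missing_rate, c(n2, p, k))

    target <- longitudinal_cohort(target_values, mask_t, target_ids, grid,
                                  sprintf("f%03d", seq_len(k)))
    background <- longitudinal_cohort(background_values, mask_b,
                                      background_ids, grid,
                                      sprintf("f%03d", seq_len(k)))

    # progression labels: latent = slope * disease score + logistic noise,
    # thresholds at sample quantiles matching the requested class mix
    # (high disease burden -> "worse")
    s <- as.numeric(scale(z_dis[, 1]))
    latent <- spec$label_slope * s + stats::rlogis(n1)
    n_worse <- round(spec$label_proportions[["-1"]] * n1)
    n_better <- round(spec$label_proportions[["1"]] * n1)
    r <- rank(latent, ties.method = "first")
    label <- rep(0L, n1)
    label[r > n1 - n_worse] <- -1L
    label[r <= n_better] <- 1L
    labels <- progression_labels(target_ids, label, horizon_years = 1)

    structure(list(
      pair = cohort_pair(target, background),
      truth = list(labels = labels,
                   subtype = stats::setNames(subtype, target_ids),
                   u_age = u_age, u_dis = u_dis,
                   g_age = g_age, g_dis = g_dis,
                   z_age_target = z_age_t, z_dis = z_dis),
      spec = spec), class = "synthetic_cohorts")
  })
}

#' @export
print.synthetic_cohorts <- function(x, ...) {
  cat("<synthetic_cohorts>\n")
  print(x$pair)
  cat(sprintf("  planted: %d aging axis/es (share %.2f), %d disease axis/es (share %.2f), %d subtypes\n",
              x$spec$n_aging_axes, x$spec$sigma2_age,
              x$spec$n_disease_axes, x$spec$sigma2_dis, x$spec$n_subtypes))
  invisible(x)
}
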