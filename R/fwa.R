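#' Fireworks algorithm configuration
#'
#' The fireworks algorithm is a population optimizer: each "firework" explodes
#' into displacement "sparks", better fireworks earn more sparks on smaller
#' explosion amplitudes (local refinement) while worse ones throw fewer sparks
#' farther (exploration); a handful of Gaussian-mutation sparks add diversity,
#' out-of-bounds sparks are mapped back into the box, and the next generation
#' keeps the elite best plus individuals chosen by distance-weighted roulette.
#'
#' @param bounds 2-column matrix (or list of length-2 vectors), one row per
#'   dimension: lower, upper.
#' @param n_fireworks Population size (>= 2).
#' @param total_sparks Total explosion sparks per generation.
#' @param amplitude_max Maximum explosion amplitude; defaults to the largest
#'   box side.
#' @param spark_min,spark_max Clamps on per-firework spark counts.
#' @param n_gaussian Gaussian-mutation sparks per generation.
#' @param max_evaluations Objective evaluation budget.
#' @param seed Integer seed; the whole run is reproducible given the seed.
#' @return An object of class `fwa_config`.
#' @export
fwa_config <- function(bounds, n_fireworks = 5, total_sparks = 30,
                       amplitude_max = NULL, spark_min = 2, spark_max = 15,
                       n_gaussian = 5, max_evaluations = 2000, seed = 1) {
  if (is.list(bounds)) bounds <- do.call(rbind, bounds)
  bounds <- matrix(as.numeric(bounds), ncol = 2)
  assert_that(all(bounds[, 1] <= bounds[, 2]),
              "bounds must satisfy low <= high per dimension")
  assert_that(n_fireworks >= 2, "`n_fireworks` must be >= 2")
  assert_that(spark_min <= spark_max && spark_max <= total_sparks,
              "need spark_min <= spark_max <= total_sparks")
  if (is.null(amplitude_max)) amplitude_max <- max(bounds[, 2] - bounds[, 1], 1e-8)
  structure(list(bounds = bounds, n_fireworks = as.integer(n_fireworks),
                 total_sparks = as.integer(total_sparks),
                 amplitude_max = amplitude_max,
                 spark_min = as.integer(spark_min),
                 spark_max = as.integer(spark_max),
                 n_gaussian = as.integer(n_gaussian),
                 max_evaluations = as.integer(max_evaluations),
                 seed = as.integer(seed)),
            class = "fwa_config")
}

# Modular mapping of out-of-bounds coordinates back into the box.
fwa_map_back <- function(x, bounds) {
  for (j in seq_along(x)) {
    lo <- bounds[j, 1]; hi <- bounds[j, 2]
    if (hi - lo < 1e-12) { x[j] <- lo; next }
    if (x[j] < lo || x[j] > hi) x[j] <- lo + abs(x[j] - lo) %% (hi - lo)
  }
  x
}

#' Maximize an objective with the fireworks algorithm
#'
#' Canonical fireworks loop under a fixed evaluation budget; elitism makes the
#' per-generation best value non-decreasing, and identical seeds give
#' identical results.
#'
#' @param objective Function mapping a numeric vector (one point in the box)
#'   to a finite scalar; maximized.
#' @param config An [fwa_config()].
#' @return An object of class `fwa_result`: `best_point`, `best_value`,
#'   `history` (per-generation best), `evaluations_used`.
#' @export
fwa_optimize <- function(objective, config) {
  assert_that(inherits(config, "fwa_config"), "`config` must be an fwa_config")
  bounds <- config$bounds
  dims <- nrow(bounds)
  eps <- .Machine$double.eps
  n_eval <- 0L
  eval_obj <- function(x) {
    v <- objective(x)
    if (!is_number(v)) {
      rlang::abort(sprintf("objective returned a non-finite value at (%s)",
                           paste(signif(x, 6), collapse = ", ")))
    }
    n_eval <<- n_eval + 1L
    v
  }
  with_local_seed(config$seed, {
    pop <- t(vapply(seq_len(config$n_fireworks), function(i) {
      stats::runif(dims, bounds[, 1], bounds[, 2])
    }, numeric(dims)))
    fit <- apply(pop, 1, eval_obj)
    history <- max(fit)
    while (n_eval < config$max_evaluations) {
      budget_left <- config$max_evaluations - n_eval
      f_min <- min(fit); f_max <- max(fit)
      # fitness-proportional spark counts, inverse-fitness amplitudes
      s_raw <- config$total_sparks * (fit - f_min + eps) / sum(fit - f_min + eps)
      s_cnt <- pmin(pmax(round(s_raw), config$spark_min), config$spark_max)
      amp <- config$amplitude_max * (f_max - fit + eps) / sum(f_max - fit + eps)
      # decaying lower amplitude bound: the raw rule gives the best firework a
      # near-zero radius, which stalls refinement; shrink the floor with the
      # spent budget so late generations search finely around the elite
      frac <- n_eval / config$max_evaluations
      amp_min <- config$amplitude_max * (0.05 * (1 - frac) + 1e-4)
      amp <- pmax(amp, amp_min)
      cand_x <- list(); cand_f <- numeric(0)
      done <- FALSE
      for (i in seq_len(nrow(pop))) {
        for (s in seq_len(s_cnt[i])) {
          if (length(cand_f) >= budget_left) { done <- TRUE; break }
          z <- sample.int(dims, size = sample.int(dims, 1))
          x <- pop[i, ]
          x[z] <- x[z] + stats::runif(length(z), -amp[i], amp[i])
          x <- fwa_map_back(x, bounds)
          cand_x[[length(cand_x) + 1L]] <- x
          cand_f <- c(cand_f, eval_obj(x))
        }
        if (done) break
      }
      if (!done) {
        for (g in seq_len(config$n_gaussian)) {
          if (length(cand_f) >= budget_left) break
          i <- sample.int(nrow(pop), 1)
          z <- sample.int(dims, size = sample.int(dims, 1))
          x <- pop[i, ]
          x[z] <- x[z] * stats::rnorm(length(z), mean = 1, sd = 1)
          x <- fwa_map_back(x, bounds)
          cand_x[[length(cand_x) + 1L]] <- x
          cand_f <- c(cand_f, eval_obj(x))
        }
      }
      all_x <- rbind(pop, do.call(rbind, cand_x))
      all_f <- c(fit, cand_f)
      best <- which.max(all_f)
      n_keep <- min(config$n_fireworks, nrow(all_x))
      others <- setdiff(seq_len(nrow(all_x)), best)
      # distance-weighted roulette: crowded points are less likely to survive
      dmat <- as.matrix(stats::dist(all_x))
      wt <- rowSums(dmat)[others]
      pick <- if (length(others) <= n_keep - 1L) {
        others
      } else if (sum(wt) < 1e-300) {
        sample(others, n_keep - 1L)
      } else {
        sample(others, n_keep - 1L, prob = wt / sum(wt))
      }
      sel <- c(best, pick)
      pop <- all_x[sel, , drop = FALSE]
      fit <- all_f[sel]
      history <- c(history, max(fit))
      if (length(cand_f) == 0L) break  # degenerate budget: nothing evaluable
    }
    best <- which.max(fit)
    structure(list(best_point = pop[best, ], best_value = fit[best],
                   history = history, evaluations_used = n_eval,
                   n_generations = length(history)),
              class = "fwa_result")
  })
}

#' @export
print.fwa_result <- function(x, ...) {
  cat(sprintf("<fwa_result> best value %.6g at (%s) after %d evaluations, %d generations\n",
              x$best_value, paste(signif(x$best_point, 6), collapse = ", "),
              x$evaluations_used, x$n_generations))
  invisible(x)
}

#' Tune T-cPCA contrast strengths with the fireworks algorithm
#'
#' Searches (alpha_feature, alpha_time) in log10 space (default bounds
#' `[1e-2, 1e3]` per axis) maximizing the mean stratified 3-fold
#' cross-validated accuracy (optionally macro-F1) of a classifier on the
#' T-cPCA representation; CV folds are seeded once, so every candidate is
#' scored on identical splits.
#'
#' @param pair A standardized `cohort_pair`.
#' @param labels A `progression_labels` object for the target cohort.
#' @param classifier A [classifier_spec()]; default 5-nearest-neighbours
#'   (fast and parameter-free, suited to a tuning inner loop).
#' @param config An [fwa_config()] over log10-alpha space; `NULL` uses
#'   default bounds with a modest budget.
#' @param metric `"accuracy"` or `"macro_f1"`.
#' @param n_folds Stratified folds for the objective (default 3).
#' @param energy Rank-selection energy passed to [fit_tcpca()].
#' @return List with `alpha_feature`, `alpha_time` and the full `fwa_result`
#'   (in log10 coordinates).
#' @export
tune_alphas <- function(pair, labels, classifier = classifier_spec("knn"),
                        config = NULL, metric = c("accuracy", "macro_f1"),
                        n_folds = 3, energy = 0.9) {
  metric <- match.arg(metric)
  y <- labels_factor(labels, pair$target$subject_ids)
  assert_that(nlevels(droplevels(y)) >= 2,
              "degenerate labels: tuning needs at least two classes")
  if (is.null(config)) {
    config <- fwa_config(bounds = rbind(c(-2, 3), c(-2, 3)),
                         max_evaluations = 60, total_sparks = 12,
                         n_fireworks = 4, spark_max = 6, n_gaussian = 2)
  }
  fold_seed <- derive_seed(config$seed, "tune-folds")
  folds <- with_local_seed(fold_seed, stratified_folds(y, n_folds, strict = FALSE))
  objective <- function(point) {
    alphas <- 10^point
    fit <- fit_tcpca(pair, alpha_feature = alphas[1], alpha_time = alphas[2],
                     energy = energy)
    x <- predict(fit, pair$target)$flat
    scores <- cv_fold_scores(x, y, folds, classifier,
                             seed = derive_seed(config$seed, "tune-clf"))
    mean(scores[[if (metric == "accuracy") "acc" else "f1"]])
  }
  res <- fwa_optimize(objective, config)
  list(alpha_feature = 10^res$best_point[1], alpha_time = 10^res$best_point[2],
       result = res)
}
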