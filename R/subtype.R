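#' Hierarchical subtype discovery with silhouette model selection
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances by default)
#' of the flattened representation, cut at every K in `k_range`; the mean
#' silhouette width is computed per K and the maximizing K is selected (ties
#' go to the smaller K).
#'
#' @param rep A `tcpca_representation`, `feature_table`, or numeric matrix.
#' @param k_range Candidate cluster counts (default 2:10).
#' @param linkage An [stats::hclust()] method (default `"ward.D2"`,
#'   configurable to `"complete"` or `"average"`).
#' @return An object of class `subtype_model`: `n_clusters`, `assignments`
#'   (named integer vector), `silhouette_by_k` tibble, `linkage`, and the
#'   underlying `hclust` tree.
#' @export
fit_subtypes <- function(rep, k_range = 2:10, linkage = "ward.D2") {
  x <- rep_matrix(rep)
  n <- nrow(x)
  assert_that(n >= max(k_range) + 1,
              "need N >= max(k_range) + 1 subjects")
  d <- stats::dist(x)
  assert_that(max(d) > 0, "all points identical: silhouette is undefined")
  hc <- stats::hclust(d, method = linkage)
  sil <- vapply(k_range, function(k) {
    mean(cluster::silhouette(stats::cutree(hc, k), d)[, "sil_width"])
  }, numeric(1))
  best_k <- k_range[which.max(sil)]  # which.max takes the first (smallest K) on ties
  assignments <- stats::cutree(hc, best_k)
  names(assignments) <- rownames(x) %||% as.character(seq_len(n))
  structure(list(n_clusters = best_k, assignments = assignments,
                 silhouette_by_k = tibble::tibble(k = k_range, silhouette = sil),
                 linkage = list(method = linkage, metric = "euclidean"),
                 hclust = hc),
            class = "subtype_model")
}

rep_matrix <- function(rep) {
  if (inherits(rep, "tcpca_representation")) {
    x <- rep$flat
    rownames(x) <- rep$subject_ids
    x
  } else {
    ft_matrix(rep)
  }
}

#' @export
print.subtype_model <- function(x, ...) {
  cat(sprintf("<subtype_model> K = %d (%s linkage), sizes: %s\n",
              x$n_clusters, x$linkage$method,
              paste(table(x$assignments), collapse = ", ")))
  cat(sprintf("  mean silhouette at K: %.3f\n",
              x$silhouette_by_k$silhouette[x$silhouette_by_k$k == x$n_clusters]))
  invisible(x)
}

#' @export
tidy.subtype_model <- function(x, ...) {
  tibble::tibble(subject_id = names(x$assignments),
                 cluster = unname(x$assignments))
}

#' @export
glance.subtype_model <- function(x, ...) {
  tibble::tibble(n_clusters = x$n_clusters,
                 silhouette = max(x$silhouette_by_k$silhouette),
                 linkage = x$linkage$method)
}

#' Silhouette model-selection curve
#'
#' @param object A `subtype_model`.
#' @param ... Unused.
#' @export
autoplot.subtype_model <- function(object, ...) {
  df <- object$silhouette_by_k
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$silhouette)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$n_clusters, linetype = 2,
                        colour = "firebrick") +
    ggplot2::scale_x_continuous(breaks = df$k) +
    ggplot2::labs(x = "number of clusters K", y = "mean silhouette width") +
    ggplot2::theme_minimal()
}

#' Before/after-clustering prediction comparison
#'
#' "Before" is pooled cross-validated prediction on the whole representation;
#' "after" fits the same classifier with identical hyperparameters within
#' each cluster and aggregates the per-cluster metrics weighted by cluster
#' size. Clusters with fewer members than folds or with a single label class
#' are merged into the cluster with the nearest centroid (with a warning)
#' before evaluation. With K = 1 the two phases coincide exactly.
#'
#' @param rep Representation accepted by [fit_subtypes()].
#' @param labels A `progression_labels` object.
#' @param model A `subtype_model` (or integer assignment vector).
#' @param classifier A [classifier_spec()].
#' @param n_folds,n_runs Cross-validation layout (defaults 3 x 10).
#' @param seed Master seed (shared by both phases).
#' @return An object of class `cluster_eval`: `$summary` (phase x metric),
#'   `$by_cluster`, and the per-phase fold scores.
#' @export
per_cluster_evaluation <- function(rep, labels, model,
                                   classifier = classifier_spec("knn"),
                                   n_folds = 3, n_runs = 10, seed = 1) {
  x <- rep_matrix(rep)
  assignments <- if (inherits(model, "subtype_model")) model$assignments
                 else as.integer(model)
  assert_that(length(assignments) == nrow(x),
              "one cluster assignment per subject required")
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  y <- labels_factor(labels, ids)
  assert_that(length(y) > 0, "no overlap between labels and assignments")

  assignments <- merge_small_clusters(x, y, assignments, n_folds)

  run_cv <- function(rows) {
    purrr::map_dfr(seq_len(n_runs), function(r) {
      folds <- with_local_seed(derive_seed(seed, paste0("folds-run", r)),
                               stratified_folds(droplevels(y[rows]), n_folds,
                                                strict = FALSE))
      sc <- cv_fold_scores(x[rows, , drop = FALSE], droplevels(y[rows]), folds,
                           classifier, seed = derive_seed(seed, paste0("clf-run", r)))
      dplyr::mutate(sc, run = r, .before = 1)
    })
  }
  before_scores <- run_cv(seq_len(nrow(x)))
  clusters <- sort(unique(assignments))
  by_cluster <- purrr::map_dfr(clusters, function(cl) {
    rows <- which(assignments == cl)
    sc <- run_cv(rows)
    tibble::tibble(cluster = cl, n = length(rows),
                   acc = mean(sc$acc), recall = mean(sc$recall),
                   f1 = mean(sc$f1),
                   acc_sd = stats::sd(sc$acc))
  })
  w <- by_cluster$n / sum(by_cluster$n)
  summary <- tibble::tibble(
    phase = c("before", "after"),
    acc = c(mean(before_scores$acc), sum(w * by_cluster$acc)),
    recall = c(mean(before_scores$recall), sum(w * by_cluster$recall)),
    f1 = c(mean(before_scores$f1), sum(w * by_cluster$f1)))
  structure(list(summary = summary, by_cluster = by_cluster,
                 before_scores = before_scores,
                 assignments = assignments, classifier = classifier,
                 n_folds = n_folds, n_runs = n_runs, seed = seed),
            class = "cluster_eval")
}

# Merge clusters that cannot sustain stratified CV (too few members or a
# single label class) into the cluster with the nearest centroid.
merge_small_clusters <- function(x, y, assignments, n_folds) {
  repeat {
    clusters <- sort(unique(assignments))
    if (length(clusters) <= 1L) break
    sizes <- table(factor(assignments, levels = clusters))
    bad <- NULL
    for (cl in clusters) {
      rows <- which(assignments == cl)
      if (length(rows) < n_folds ||
          nlevels(droplevels(y[rows])) < 2L) { bad <- cl; break }
    }
    if (is.null(bad)) break
    centroids <- t(vapply(clusters, function(cl) {
      colMeans(x[assignments == cl, , drop = FALSE])
    }, numeric(ncol(x))))
    own <- which(clusters == bad)
    dist_to <- sqrt(rowSums(sweep(centroids, 2, centroids[own, ])^2))
    dist_to[own] <- Inf
    target <- clusters[which.min(dist_to)]
    rlang::warn(sprintf(
      "per_cluster_evaluation: merging cluster %s (too small or single-class) into cluster %s",
      bad, target))
    assignments[assignments == bad] <- target
  }
  assignments
}

#' @export
print.cluster_eval <- function(x, ...) {
  cat(sprintf("<cluster_eval> %s, %d clusters, %d folds x %d runs\n",
              x$classifier$name, nrow(x$by_cluster), x$n_folds, x$n_runs))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.cluster_eval <- function(x, ...) {
  tidyr::pivot_longer(x$summary, -"phase", names_to = "metric")
}
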