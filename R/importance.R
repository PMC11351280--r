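#' Gini impurity of a node
#'
#' For class proportions p_1..p_C at a node, the Gini index is
#' 1 - sum_c p_c^2 (equivalently sum over pairs of distinct classes of
#' p_c * p_c').
#'
#' @param class_proportions Nonnegative vector summing to 1 (within 1e-9).
#' @return The impurity, a number in \[0, 1 - 1/C\].
#' @export
node_gini <- function(class_proportions) {
  p <- as.numeric(class_proportions)
  assert_that(all(p >= 0) && abs(sum(p) - 1) <= 1e-9,
              "`class_proportions` must be a simplex vector (nonnegative, sum 1)")
  1 - sum(p^2)
}

#' Fit a random forest that records what Gini importance needs
#'
#' A thin wrapper around [ranger::ranger()] keeping the in-bag counts so that
#' per-node class counts can be reconstructed by routing the training samples
#' through each tree. Defaults: 500 trees, sqrt(k) candidate features per
#' split.
#'
#' @param x Numeric matrix or data frame of predictors (N x k).
#' @param y Class labels (coerced to factor).
#' @param n_trees Number of trees (default 500).
#' @param mtry Candidate features per split; default `floor(sqrt(k))`.
#' @param seed Integer seed.
#' @param ... Passed on to [ranger::ranger()].
#' @return An object of class `gini_forest` wrapping the ranger fit together
#'   with the training data.
#' @export
fit_gini_forest <- function(x, y, n_trees = 500, mtry = NULL, seed = 1, ...) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- droplevels(as.factor(y))
  assert_that(nlevels(y) >= 2, "forest fitting needs at least two classes")
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  df <- as.data.frame(x)
  fit <- ranger::ranger(y = y, x = df, num.trees = n_trees,
                        mtry = min(mtry, ncol(x)), keep.inbag = TRUE,
                        seed = seed, num.threads = 1, ...)
  structure(list(forest = fit, x = x, y = y, n_trees = n_trees),
            class = "gini_forest")
}

# Route the (in-bag-weighted) training samples of one tree through its
# recorded splits, returning per-node class counts plus the split layout.
tree_node_counts <- function(tree_info, x, y, inbag) {
  n_nodes <- nrow(tree_info)
  counts <- matrix(0, nrow = n_nodes, ncol = nlevels(y))
  active <- inbag > 0
  node_of <- rep(1L, nrow(x))         # 1-based row into tree_info
  repeat {
    tallied <- tapply(inbag[active], list(node_of[active], y[active]), sum)
    rn <- as.integer(rownames(tallied))
    tallied[is.na(tallied)] <- 0
    counts[rn, ] <- counts[rn, , drop = FALSE] + tallied
    movable <- active & !tree_info$terminal[node_of]
    if (!any(movable)) break
    mi <- which(movable)
    sv <- tree_info$splitvarID[node_of[mi]] + 1L          # 0-based -> column
    xv <- x[cbind(mi, sv)]
    go_left <- xv <= tree_info$splitval[node_of[mi]]
    node_of[mi] <- ifelse(go_left,
                          tree_info$leftChild[node_of[mi]] + 1L,
                          tree_info$rightChild[node_of[mi]] + 1L)
    active <- logical(nrow(x)); active[mi] <- TRUE
  }
  counts
}

#' Forest Gini importance
#'
#' Accumulates, for every split on feature x_j, the change of node impurity
#' GI_parent - GI_left - GI_right, summed over a feature's occurrences within
#' each tree and over all trees. The default is this literal unweighted child
#' subtraction; `weighted = TRUE` instead uses the conventional
#' sample-weighted impurity decrease
#' (n_parent GI_parent - n_left GI_left - n_right GI_right) / n_root.
#' With `normalize = TRUE` scores are divided by their total so they sum to 1.
#'
#' @param forest A `gini_forest` from [fit_gini_forest()].
#' @param normalize Normalize scores to sum 1 (default TRUE).
#' @param weighted Use the sample-weighted impurity decrease instead of the
#'   literal unweighted form (default FALSE).
#' @return An object of class `gini_importance`: tibble `$scores` (feature,
#'   score) plus fields `normalized`, `n_trees`, `class_count`.
#' @export
forest_gini_importance <- function(forest, normalize = TRUE, weighted = FALSE) {
  assert_that(inherits(forest, "gini_forest"),
              "`forest` must come from fit_gini_forest()")
  if (is.null(forest$forest$inbag.counts)) {
    rlang::abort("forest lacks recorded in-bag counts; refit with fit_gini_forest()")
  }
  k <- ncol(forest$x)
  vim <- numeric(k)
  for (t in seq_len(forest$n_trees)) {
    ti <- ranger::treeInfo(forest$forest, t)
    inbag <- forest$forest$inbag.counts[[t]]
    counts <- tree_node_counts(ti, forest$x, forest$y, inbag)
    n_node <- rowSums(counts)
    gi <- apply(counts, 1, function(cnt) {
      tot <- sum(cnt)
      if (tot == 0) return(NA_real_)
      1 - sum((cnt / tot)^2)
    })
    internal <- which(!ti$terminal)
    for (q in internal) {
      l <- ti$leftChild[q] + 1L; r <- ti$rightChild[q] + 1L
      if (is.na(gi[q]) || is.na(gi[l]) || is.na(gi[r])) next
      j <- ti$splitvarID[q] + 1L
      vim[j] <- vim[j] + if (weighted) {
        (n_node[q] * gi[q] - n_node[l] * gi[l] - n_node[r] * gi[r]) / n_node[1L]
      } else {
        gi[q] - gi[l] - gi[r]
      }
    }
  }
  # the unweighted child subtraction can net out negative for a feature when
  # splits leave both children nearly as impure as the parent; scores are
  # clamped at zero so importances stay a (normalizable) nonnegative profile
  if (!weighted) vim <- pmax(vim, 0)
  if (normalize) {
    tot <- sum(vim)
    if (tot > 0) vim <- vim / tot
  }
  gini_importance(vim, colnames(forest$x), normalized = normalize,
                  n_trees = forest$n_trees, class_count = nlevels(forest$y))
}

gini_importance <- function(scores, features, normalized, n_trees, class_count) {
  structure(list(scores = tibble::tibble(feature = features,
                                         score = as.numeric(scores)),
                 normalized = normalized, n_trees = n_trees,
                 class_count = class_count),
            class = "gini_importance")
}

#' @export
print.gini_importance <- function(x, ...) {
  cat(sprintf("<gini_importance> %d features, %d trees, %d classes%s\n",
              nrow(x$scores), x$n_trees, x$class_count,
              if (x$normalized) " (normalized)" else ""))
  print(utils::head(dplyr::arrange(x$scores, dplyr::desc(.data$score)), 10))
  invisible(x)
}

#' @export
tidy.gini_importance <- function(x, ...) x$scores

#' Convenience: Gini importance of labels on a feature matrix
#'
#' Fits a forest with [fit_gini_forest()] and scores it with
#' [forest_gini_importance()].
#'
#' @inheritParams fit_gini_forest
#' @inheritParams forest_gini_importance
#' @return A `gini_importance`.
#' @export
gini_importance_of <- function(x, y, n_trees = 500, mtry = NULL, seed = 1,
                               normalize = TRUE, weighted = FALSE) {
  forest_gini_importance(fit_gini_forest(x, y, n_trees = n_trees, mtry = mtry,
                                         seed = seed),
                         normalize = normalize, weighted = weighted)
}

#' Representative features above an importance threshold
#'
#' Features whose normalized Gini importance is strictly greater than the
#' threshold (default 0.02), in descending score order.
#'
#' @param imp A normalized `gini_importance`.
#' @param threshold Exclusive lower bound on the score (default 0.02).
#' @return Tibble (feature, score) sorted by descending score.
#' @export
representative_features <- function(imp, threshold = 0.02) {
  assert_that(inherits(imp, "gini_importance"), "`imp` must be a gini_importance")
  assert_that(isTRUE(imp$normalized),
              "representative features require normalized importance scores")
  out <- dplyr::filter(imp$scores, .data$score > threshold)
  dplyr::arrange(out, dplyr::desc(.data$score))
}

#' Per-visit longitudinal importance profile
#'
#' Fits a fresh seeded forest on each visit's N x k slice and records its
#' normalized importance as one row, yielding a p x k profile of when each
#' feature matters.
#'
#' @param cohort A fully observed `longitudinal_cohort`.
#' @param labels A `progression_labels` object or per-subject class vector.
#' @param n_trees Trees per visit-level forest (default 200).
#' @param mtry Candidate features per split (default sqrt(k)).
#' @param seed Master seed; visit t uses a seed derived from it.
#' @return An object of class `longitudinal_importance` with matrix
#'   `$profile` (p x k, rows summing to 1).
#' @export
longitudinal_importance <- function(cohort, labels, n_trees = 200, mtry = NULL,
                                    seed = 1) {
  assert_that(all(cohort$mask), "each visit slice must be complete")
  y <- if (inherits(labels, "progression_labels")) {
    labels_factor(labels, cohort$subject_ids)
  } else {
    as.factor(labels)
  }
  assert_that(nlevels(droplevels(y)) >= 2,
              "longitudinal importance needs at least two classes")
  d <- dim(cohort$values)
  profile <- matrix(0, nrow = d[2], ncol = d[3],
                    dimnames = list(cohort$visit_grid$label, cohort$feature_names))
  for (t in seq_len(d[2])) {
    slice <- matrix(cohort$values[, t, ], nrow = d[1], ncol = d[3])
    colnames(slice) <- cohort$feature_names
    imp <- gini_importance_of(slice, y, n_trees = n_trees, mtry = mtry,
                              seed = derive_seed(seed, paste0("visit", t)))
    profile[t, ] <- imp$scores$score
  }
  structure(list(profile = profile, visit_grid = cohort$visit_grid,
                 feature_names = cohort$feature_names, n_trees = n_trees),
            class = "longitudinal_importance")
}

#' @export
print.longitudinal_importance <- function(x, ...) {
  cat(sprintf("<longitudinal_importance> %d visits x %d features (%d trees per visit)\n",
              nrow(x$profile), ncol(x$profile), x$n_trees))
  invisible(x)
}

#' @export
tidy.longitudinal_importance <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$profile), rownames = NA) |>
    dplyr::mutate(visit = rownames(x$profile), .before = 1) |>
    tidyr::pivot_longer(-"visit", names_to = "feature", values_to = "score")
}

#' Importance bar / heatmap plots
#'
#' @param object A `gini_importance` or `longitudinal_importance`.
#' @param top_n How many features to show (default 20).
#' @param ... Unused.
#' @export
autoplot.gini_importance <- function(object, top_n = 20, ...) {
  df <- dplyr::slice_max(object$scores, .data$score, n = top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$feature, .data$score),
                                   y = .data$score)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "normalized Gini importance") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.gini_importance
#' @export
autoplot.longitudinal_importance <- function(object, top_n = 20, ...) {
  keep <- names(sort(colSums(object$profile), decreasing = TRUE))[
    seq_len(min(top_n, ncol(object$profile)))]
  df <- tidy.longitudinal_importance(object)
  df <- df[df$feature %in% keep, ]
  df$visit <- factor(df$visit, levels = object$visit_grid$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$visit, y = .data$feature,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "visit", y = NULL, fill = "importance") +
    ggplot2::theme_minimal()
}
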