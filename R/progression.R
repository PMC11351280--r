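#' Progression labels
#'
#' Three-class outcome comparing the ordinal diagnosis (CN = 0 < MCI = 1 <
#' dementia = 2) at the end of the observation window with the diagnosis at a
#' 1-, 3- or 5-year horizon: a lower future status is "better" (+1), a higher
#' one "worse" (-1), an unchanged one 0.
#'
#' @param status Data frame with columns `subject_id`, `month`, `status`
#'   (ordinal codes over calendar time).
#' @param horizon_years Prediction span; one of 1, 3, 5.
#' @param baseline_month Month at which the observation window ends (default
#'   42, the last visit of [default_visit_grid()]).
#' @param tolerance Maximum |month difference| when matching the required
#'   time points (default 0: exact match).
#' @return An object of class `progression_labels`: a tibble `subject_id`,
#'   `label` with attributes `horizon_years`, `class_counts`, `n_dropped`.
#'   Subjects missing either status are dropped and counted.
#' @export
make_progression_labels <- function(status, horizon_years, baseline_month = 42,
                                    tolerance = 0) {
  assert_that(horizon_years %in% c(1, 3, 5),
              "`horizon_years` must be one of 1, 3, 5")
  status <- tibble::as_tibble(status)
  assert_that(all(c("subject_id", "month", "status") %in% names(status)),
              "`status` needs columns subject_id, month, status")
  horizon_month <- baseline_month + 12 * horizon_years
  at <- function(df, m) {
    df <- df[abs(df$month - m) <= tolerance, , drop = FALSE]
    if (nrow(df) == 0L) return(NA_integer_)
    as.integer(df$status[which.min(abs(df$month - m))])
  }
  per <- status |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(now = at(dplyr::pick(dplyr::everything()), baseline_month),
                     future = at(dplyr::pick(dplyr::everything()), horizon_month),
                     .groups = "drop")
  dropped <- sum(is.na(per$now) | is.na(per$future))
  per <- per[!is.na(per$now) & !is.na(per$future), , drop = FALSE]
  if (dropped > 0) {
    rlang::inform(sprintf(
      "make_progression_labels: dropped %d subject(s) without a status at the horizon",
      dropped))
  }
  label <- ifelse(per$future < per$now, 1L, ifelse(per$future > per$now, -1L, 0L))
  progression_labels(per$subject_id, label, horizon_years, n_dropped = dropped)
}

#' Construct a progression label set directly
#'
#' @param subject_ids Subject identifiers.
#' @param label Integer labels in -1 (worse), 0 (unchanged), +1 (better).
#' @param horizon_years One of 1, 3, 5.
#' @param n_dropped Subjects excluded for missing horizon status.
#' @return A `progression_labels` tibble.
#' @export
progression_labels <- function(subject_ids, label, horizon_years,
                               n_dropped = 0L) {
  label <- as.integer(label)
  assert_that(all(label %in% c(-1L, 0L, 1L)),
              "labels must come from {-1, 0, +1}")
  assert_that(horizon_years %in% c(1, 3, 5),
              "`horizon_years` must be one of 1, 3, 5")
  out <- tibble::tibble(subject_id = as.character(subject_ids), label = label)
  attr(out, "horizon_years") <- horizon_years
  attr(out, "class_counts") <- c(`-1` = sum(label == -1L), `0` = sum(label == 0L),
                                 `1` = sum(label == 1L))
  attr(out, "n_dropped") <- as.integer(n_dropped)
  class(out) <- c("progression_labels", class(out))
  out
}

#' @export
print.progression_labels <- function(x, ...) {
  cc <- attr(x, "class_counts")
  cat(sprintf("<progression_labels> horizon %d y: worse %d / unchanged %d / better %d (%d dropped)\n",
              attr(x, "horizon_years"), cc[["-1"]], cc[["0"]], cc[["1"]],
              attr(x, "n_dropped")))
  invisible(x)
}

# Factor of labels aligned to a vector of subject ids (levels -1, 0, 1).
labels_factor <- function(labels, subject_ids) {
  idx <- match(as.character(subject_ids), labels$subject_id)
  assert_that(!anyNA(idx), "labels missing for some subjects")
  factor(labels$label[idx], levels = c(-1L, 0L, 1L))
}

#' Classifier specifications
#'
#' The three supervised learners used throughout the evaluation harness, with
#' their recorded hyperparameters: a single-hidden-layer perceptron
#' (`size = 100`, `maxit = 100`, `decay = 0`), a random forest
#' (`num_trees = 500`) and k-nearest neighbours (`k = 5`).
#'
#' @param name `"mlp"`, `"rf"` or `"knn"`.
#' @param ... Hyperparameter overrides (`size`, `maxit`, `decay`;
#'   `num_trees`, `mtry`; `k`).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("mlp", "rf", "knn"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    mlp = list(size = 100, maxit = 100, decay = 0, max_weights = 5000),
    rf = list(num_trees = 500, mtry = NULL),
    knn = list(k = 5))
  params <- utils::modifyList(defaults, list(...))
  structure(list(name = name, params = params), class = "classifier_spec")
}

# Fit on (x, y) and predict classes for newx; deterministic given seed.
fit_predict <- function(spec, x, y, newx, seed) {
  lv <- levels(y)
  p <- spec$params
  pred <- switch(spec$name,
    mlp = with_local_seed(seed, {
      ymat <- nnet::class.ind(y)
      # quasi-Newton training in nnet stores an O(weights^2) Hessian
      # approximation, so the hidden layer shrinks on very wide inputs to
      # respect the total weight budget
      size <- min(p$size,
                  max(2L, (p$max_weights - ncol(ymat)) %/%
                        (ncol(x) + 1L + ncol(ymat))))
      nw <- (ncol(x) + 1) * size + (size + 1) * ncol(ymat)
      fit <- nnet::nnet(x = x, y = ymat, size = size, softmax = TRUE,
                        maxit = p$maxit, decay = p$decay, trace = FALSE,
                        MaxNWts = nw + 1)
      cls <- colnames(ymat)[max.col(stats::predict(fit, newx))]
      factor(cls, levels = lv)
    }),
    rf = with_local_seed(seed, {   # ranger breaks vote ties via the R RNG
      mtry <- p$mtry %||% max(1L, floor(sqrt(ncol(x))))
      df <- as.data.frame(x); colnames(df) <- paste0("V", seq_len(ncol(x)))
      nd <- as.data.frame(newx); colnames(nd) <- colnames(df)
      fit <- ranger::ranger(y = y, x = df, num.trees = p$num_trees,
                            mtry = min(mtry, ncol(x)), seed = seed,
                            num.threads = 1)
      factor(stats::predict(fit, nd, num.threads = 1)$predictions, levels = lv)
    }),
    knn = with_local_seed(seed, {
      factor(as.character(class::knn(train = x, test = newx, cl = y,
                                     k = min(p$k, nrow(x)))), levels = lv)
    }))
  pred
}

# Accuracy, macro recall, macro F1 over the classes present in `truth`.
classification_metrics <- function(truth, pred) {
  acc <- mean(pred == truth)
  classes <- levels(truth)[table(truth) > 0]
  rec <- f1 <- numeric(length(classes))
  for (j in seq_along(classes)) {
    cl <- classes[j]
    tp <- sum(truth == cl & pred == cl)
    recall <- tp / sum(truth == cl)
    precision <- if (sum(pred == cl) == 0) 0 else tp / sum(pred == cl)
    rec[j] <- recall
    f1[j] <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
  }
  c(acc = acc, recall = mean(rec), f1 = mean(f1))
}

# Stratified fold assignment: within each class, shuffled members are dealt
# round-robin to folds, so per-fold class counts deviate from exact
# proportionality by at most 1. `strict` errors when a class has fewer
# members than folds.
stratified_folds <- function(y, n_folds, strict = TRUE) {
  folds <- integer(length(y))
  for (cl in levels(droplevels(y))) {
    idx <- which(y == cl)
    if (strict && length(idx) < n_folds) {
      rlang::abort(sprintf(
        "class %s has %d member(s) < %d folds; reduce the fold count",
        cl, length(idx), n_folds))
    }
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

# Per-fold metric rows for one fold assignment.
cv_fold_scores <- function(x, y, folds, spec, seed) {
  out <- vector("list", max(folds))
  for (f in seq_len(max(folds))) {
    test <- folds == f
    if (!any(test) || all(test)) next
    ytr <- droplevels(y[!test])
    if (nlevels(ytr) < 2) next
    pred <- fit_predict(spec, x[!test, , drop = FALSE], ytr,
                        x[test, , drop = FALSE],
                        seed = derive_seed(seed, paste0("fold", f)))
    pred <- factor(as.character(pred), levels = levels(y))
    m <- classification_metrics(factor(y[test], levels = levels(y)), pred)
    out[[f]] <- tibble::tibble(fold = f, acc = m[["acc"]],
                               recall = m[["recall"]], f1 = m[["f1"]])
  }
  dplyr::bind_rows(out)
}

#' Repeated stratified cross-validated evaluation
#'
#' Runs `n_runs` repetitions of seeded stratified `n_folds`-fold
#' cross-validation of one classifier on one feature table; per fold, records
#' accuracy, macro-averaged recall and macro-averaged F1 over the progression
#' classes, and summarizes their mean and SD over all run x fold scores.
#' Identical master seeds give byte-identical reports.
#'
#' @param table A `feature_table` (or numeric matrix).
#' @param labels A `progression_labels` object (matched by `subject_id` when
#'   the table carries one).
#' @param classifier A [classifier_spec()].
#' @param n_folds Stratified folds (default 3).
#' @param n_runs Repetitions with different fold seeds (default 10).
#' @param seed Master seed.
#' @return An object of class `eval_entry`: `$scores` (run, fold, acc,
#'   recall, f1), `$summary` (metric, mean, sd), plus the recorded specs.
#' @export
evaluate <- function(table, labels, classifier = classifier_spec("mlp"),
                     n_folds = 3, n_runs = 10, seed = 1) {
  x <- ft_matrix(table)
  y <- if (inherits(table, "feature_table") ||
           (is.data.frame(table) && "subject_id" %in% names(table))) {
    labels_factor(labels, table$subject_id)
  } else {
    labels_factor(labels, labels$subject_id[seq_len(nrow(x))])
  }
  cc <- table(droplevels(y))
  if (any(cc < n_folds)) {
    rlang::abort(sprintf(
      "class %s has %d member(s) < %d folds; reduce the fold count",
      names(cc)[which.min(cc)], min(cc), n_folds))
  }
  scores <- purrr::map_dfr(seq_len(n_runs), function(r) {
    folds <- with_local_seed(derive_seed(seed, paste0("folds-run", r)),
                             stratified_folds(y, n_folds))
    sc <- cv_fold_scores(x, y, folds, classifier,
                         seed = derive_seed(seed, paste0("clf-run", r)))
    dplyr::mutate(sc, run = r, .before = 1)
  })
  summarise_entry(scores, classifier, n_folds, n_runs, seed,
                  provenance = attr(table, "provenance"))
}

summarise_entry <- function(scores, classifier, n_folds, n_runs, seed,
                            provenance = NULL) {
  summary <- tidyr::pivot_longer(scores, c("acc", "recall", "f1"),
                                 names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop")
  structure(list(scores = scores, summary = summary,
                 classifier = classifier, n_folds = n_folds, n_runs = n_runs,
                 seed = seed, provenance = provenance),
            class = "eval_entry")
}

#' @export
print.eval_entry <- function(x, ...) {
  cat(sprintf("<eval_entry> %s%s: %d runs x %d folds\n",
              x$classifier$name,
              if (is.null(x$provenance)) "" else paste0(" on ", x$provenance),
              x$n_runs, x$n_folds))
  print(x$summary)
  invisible(x)
}

#' Paired one-sided model comparison
#'
#' Paired t-test of mean(a - b) > 0 on fold-level score vectors sharing the
#' same (run, fold) splits. The comparison is declared significant iff the
#' p-value is at most 0.01 and the T statistic exceeds 2. Zero-variance
#' difference vectors are handled without calling the t-test: all-zero
#' differences are not significant; constant positive differences are
#' significant with a `degenerate` flag.
#'
#' @param scores_a,scores_b Equal-length numeric vectors paired by (run,
#'   fold).
#' @param alpha Significance level (default 0.01).
#' @param t_min Minimum T statistic (default 2).
#' @return A one-row tibble: `mean_diff`, `statistic`, `p_value`,
#'   `significant`, `degenerate`, `n`.
#' @export
paired_model_test <- function(scores_a, scores_b, alpha = 0.01, t_min = 2) {
  assert_that(length(scores_a) == length(scores_b),
              "score vectors must have equal length (shared folds)")
  assert_that(length(scores_a) >= 2, "need at least 2 paired scores")
  d <- scores_a - scores_b
  if (stats::sd(d) < .Machine$double.eps^0.5) {
    return(tibble::tibble(mean_diff = mean(d), statistic = NA_real_,
                          p_value = NA_real_,
                          significant = mean(d) > 0, degenerate = TRUE,
                          n = length(d)))
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE,
                      alternative = "greater")
  tibble::tibble(mean_diff = mean(d), statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 significant = tt$p.value <= alpha &&
                   unname(tt$statistic) > t_min,
                 degenerate = FALSE, n = length(d))
}

#' Full method x classifier x horizon comparison grid
#'
#' Evaluates every representation method with every classifier at every
#' horizon under shared fold seeds (so the paired tests compare scores on
#' identical splits), and tests T-cPCA against each competitor per cell with
#' the one-sided paired t-test decision rule.
#'
#' @param pair A standardized `cohort_pair`.
#' @param labels A `progression_labels` object, or a list of them (one per
#'   horizon).
#' @param methods Character vector of method tags accepted by [represent()].
#' @param classifiers List of [classifier_spec()] objects (or names).
#' @param seed Master seed shared across all cells.
#' @param n_folds,n_runs Cross-validation layout.
#' @param m Component count for subspace baselines.
#' @param alpha_feature,alpha_time Contrast strengths for the T-cPCA variants
#'   (e.g. from [tune_alphas()]).
#' @return An object of class `eval_report`: `$table` (one row per horizon x
#'   classifier x method x metric with mean, sd, and the significance of
#'   T-cPCA over that method) and `$entries` (the underlying `eval_entry`
#'   objects).
#' @export
comparison_grid <- function(pair, labels,
                            methods = c("or", "sor", "2dpca", "tcpca"),
                            classifiers = list(classifier_spec("knn")),
                            seed = 1, n_folds = 3, n_runs = 10, m = 5,
                            alpha_feature = 1, alpha_time = 1) {
  if (inherits(labels, "progression_labels")) labels <- list(labels)
  classifiers <- lapply(classifiers, function(cl) {
    if (inherits(cl, "classifier_spec")) cl else classifier_spec(cl)
  })
  reps <- lapply(methods, function(mm) {
    represent(pair, mm, m = m, alpha_feature = alpha_feature,
              alpha_time = alpha_time)
  })
  names(reps) <- methods
  entries <- list()
  rows <- list()
  for (lab in labels) {
    horizon <- attr(lab, "horizon_years")
    for (cl in classifiers) {
      cell <- lapply(reps, evaluate, labels = lab, classifier = cl,
                     n_folds = n_folds, n_runs = n_runs, seed = seed)
      for (mm in methods) {
        entries[[paste(horizon, cl$name, mm, sep = ".")]] <- cell[[mm]]
      }
      ref <- if ("tcpca" %in% methods) cell[["tcpca"]] else NULL
      for (mm in methods) {
        for (metric in c("acc", "recall", "f1")) {
          sig <- NA
          if (!is.null(ref) && mm != "tcpca") {
            tst <- paired_model_test(ref$scores[[metric]],
                                     cell[[mm]]$scores[[metric]])
            sig <- tst$significant
          }
          sm <- cell[[mm]]$summary
          rows[[length(rows) + 1L]] <- tibble::tibble(
            horizon_years = horizon, classifier = cl$name, method = mm,
            metric = metric,
            mean = sm$mean[sm$metric == metric],
            sd = sm$sd[sm$metric == metric],
            tcpca_significantly_better = sig)
        }
      }
    }
  }
  structure(list(table = dplyr::bind_rows(rows), entries = entries,
                 seed = seed, n_folds = n_folds, n_runs = n_runs),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d cells (%d folds x %d runs)\n",
              nrow(x$table) / 3, x$n_folds, x$n_runs))
  acc <- x$table[x$table$metric == "acc", ]
  wide <- tidyr::pivot_wider(acc[, c("horizon_years", "classifier", "method", "mean")],
                             names_from = "method", values_from = "mean")
  print(wide, n = Inf)
  invisible(x)
}

#' @rdname comparison_grid
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) x$table

#' @rdname comparison_grid
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$table) / 3L, n_folds = x$n_folds,
                 n_runs = x$n_runs, seed = x$seed)
}

#' Accuracy panel for an evaluation report
#'
#' @param object An `eval_report`.
#' @param metric Which metric to draw (default `"acc"`).
#' @param ... Unused.
#' @export
autoplot.eval_report <- function(object, metric = "acc", ...) {
  df <- object$table[object$table$metric == metric, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$mean,
                                   fill = .data$classifier)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           position = ggplot2::position_dodge(width = 0.9),
                           width = 0.3) +
    ggplot2::facet_wrap(~horizon_years, labeller = ggplot2::label_both) +
    ggplot2::labs(y = metric, x = NULL,
                  title = "Progression-prediction performance by representation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
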