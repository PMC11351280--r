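#' Longitudinal cohort tensors
#'
#' A `longitudinal_cohort` holds a subject x visit x feature tensor together
#' with an observation mask and metadata. One slice `values[i, , ]` is the
#' p x k clinical matrix of subject i: rows are visits on a fixed grid
#' (ordered by month offset), columns are numeric clinical features.
#'
#' @param values Numeric array of dimension N x p x k.
#' @param mask Logical array of the same dimension; `TRUE` marks observed
#'   cells. Defaults to "everything observed".
#' @param subject_ids Character or coercible vector of N unique subject ids.
#' @param visit_grid Data frame with columns `label` and `month`; months must
#'   be strictly increasing. See [visit_grid()].
#' @param feature_names Character vector of k unique feature names.
#' @param status Optional N x p integer matrix of ordinal diagnosis codes
#'   (0 = cognitively normal, 1 = mild cognitive impairment, 2 = dementia),
#'   `NA` where unknown.
#' @return An object of class `longitudinal_cohort`.
#' @export
longitudinal_cohort <- function(values, mask = NULL, subject_ids, visit_grid,
                                feature_names, status = NULL) {
  values <- as.array(values)
  d <- dim(values)
  assert_that(length(d) == 3L && all(d >= 1L),
              "`values` must be an N x p x k array with all dimensions >= 1")
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  mask <- as.array(mask)
  assert_that(identical(dim(mask), d), "`mask` must match the shape of `values`")
  storage.mode(mask) <- "logical"
  assert_that(all(is.finite(values[mask])),
              "`values` must be finite wherever `mask` is TRUE")
  subject_ids <- as.character(subject_ids)
  assert_that(length(subject_ids) == d[1L] && !anyDuplicated(subject_ids),
              "`subject_ids` must be N unique identifiers")
  visit_grid <- validate_visit_grid(visit_grid)
  assert_that(nrow(visit_grid) == d[2L],
              "`visit_grid` must have one row per visit (p)")
  feature_names <- as.character(feature_names)
  assert_that(length(feature_names) == d[3L] && !anyDuplicated(feature_names),
              "`feature_names` must be k unique names")
  if (!is.null(status)) {
    status <- as.matrix(status)
    assert_that(identical(dim(status), d[1:2]),
                "`status` must be an N x p matrix")
  }
  dimnames(values) <- list(subject_ids, visit_grid$label, feature_names)
  dimnames(mask) <- dimnames(values)
  structure(
    list(values = values, mask = mask, subject_ids = subject_ids,
         visit_grid = visit_grid, feature_names = feature_names,
         status = status),
    class = "longitudinal_cohort"
  )
}

validate_visit_grid <- function(grid) {
  grid <- tibble::as_tibble(grid)
  assert_that(all(c("label", "month") %in% names(grid)),
              "a visit grid needs columns `label` and `month`")
  assert_that(nrow(grid) >= 1L, "visit grid must not be empty")
  grid$label <- as.character(grid$label)
  grid$month <- as.numeric(grid$month)
  assert_that(!anyDuplicated(grid$label), "visit labels must be unique")
  assert_that(all(diff(grid$month) > 0),
              "visit grid month offsets must be strictly increasing")
  grid[, c("label", "month")]
}

#' Build a visit grid from month offsets
#'
#' @param months Strictly increasing numeric month offsets.
#' @param labels Optional labels; defaults to `m00`, `m06`, ...
#' @return Tibble with columns `label`, `month`.
#' @export
visit_grid <- function(months, labels = sprintf("m%02d", months)) {
  validate_visit_grid(tibble::tibble(label = labels, month = months))
}

#' Default semiannual visit grid
#'
#' Eight visits at months 0, 6, ..., 42, the grid used throughout the
#' package's examples and simulations.
#' @return Tibble with columns `label`, `month`.
#' @export
default_visit_grid <- function() visit_grid(seq(0, 42, by = 6))

#' @export
print.longitudinal_cohort <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<longitudinal_cohort> %d subjects x %d visits x %d features\n",
              d[1], d[2], d[3]))
  cat(sprintf("  visits: %s (months %s)\n",
              paste(x$visit_grid$label, collapse = ", "),
              paste(x$visit_grid$month, collapse = ", ")))
  cat(sprintf("  observed cells: %.1f%%\n", 100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.longitudinal_cohort <- function(x) dim(x$values)

#' Long-format view of a cohort
#'
#' @param x A `longitudinal_cohort`.
#' @param ... Unused.
#' @return Tibble with one row per subject-visit-feature cell.
#' @export
as_tibble.longitudinal_cohort <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(
    subject_id = rep(x$subject_ids, times = d[2] * d[3]),
    visit = rep(rep(x$visit_grid$label, each = d[1]), times = d[3]),
    month = rep(rep(x$visit_grid$month, each = d[1]), times = d[3]),
    feature = rep(x$feature_names, each = d[1] * d[2]),
    value = as.vector(x$values),
    observed = as.vector(x$mask)
  )
}

#' Pair a target (disease) cohort with a background (never-diseased) cohort
#'
#' The two cohorts must share an identical visit grid and feature set; the
#' contrastive machinery subtracts the background covariance from the target
#' covariance on both axes.
#'
#' @param target,background `longitudinal_cohort` objects.
#' @param scaling Optional scaling record (see [standardize_cohorts()]).
#' @return An object of class `cohort_pair`.
#' @export
cohort_pair <- function(target, background, scaling = NULL) {
  assert_that(inherits(target, "longitudinal_cohort") &&
                inherits(background, "longitudinal_cohort"),
              "`target` and `background` must be longitudinal_cohort objects")
  assert_that(identical(target$visit_grid, background$visit_grid),
              "target and background must share an identical visit grid")
  assert_that(identical(target$feature_names, background$feature_names),
              "target and background must share identical feature names")
  structure(list(target = target, background = background, scaling = scaling),
            class = "cohort_pair")
}

#' @export
print.cohort_pair <- function(x, ...) {
  cat("<cohort_pair>\n target:    ")
  print(x$target)
  cat(" background: ")
  print(x$background)
  if (!is.null(x$scaling)) cat(" standardized: yes\n")
  invisible(x)
}

#' Read a long-format clinical table into a cohort tensor
#'
#' Expects one row per subject-visit with an id column, a visit-label column,
#' optionally an ordinal status column, and numeric feature columns. Rows may
#' arrive in any order; subjects are sorted by id and visits by the grid, so
#' shuffled input yields an identical tensor. Subject-visit rows absent from
#' the table (and empty cells within present rows) are masked as unobserved.
#'
#' @param x A file path to a CSV (UTF-8, header row) or a data frame.
#' @param id_column,visit_column Column names for subject id and visit label.
#' @param status_column Optional column of ordinal diagnosis codes (0/1/2).
#' @param grid Visit grid (see [visit_grid()]); every visit label in the data
#'   must appear in the grid.
#' @return A `longitudinal_cohort`.
#' @export
read_cohort <- function(x, id_column = "subject_id", visit_column = "visit",
                        status_column = NULL, grid = default_visit_grid()) {
  df <- if (is.character(x) && length(x) == 1L) {
    readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble::as_tibble(x)
  }
  grid <- validate_visit_grid(grid)
  for (col in c(id_column, visit_column, status_column)) {
    assert_that(col %in% names(df), sprintf("column `%s` not found", col))
  }
  visits <- as.character(df[[visit_column]])
  unknown <- setdiff(unique(visits), grid$label)
  assert_that(length(unknown) == 0L,
              sprintf("unknown visit label(s): %s",
                      paste(unknown, collapse = ", ")))
  ids <- as.character(df[[id_column]])
  key <- paste(ids, visits, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- key[duplicated(key)][1L]
    parts <- strsplit(bad, "\r", fixed = TRUE)[[1L]]
    rlang::abort(sprintf("duplicate (subject, visit) pair: (%s, %s)",
                         parts[1L], parts[2L]))
  }
  feature_names <- setdiff(names(df), c(id_column, visit_column, status_column))
  assert_that(length(feature_names) >= 1L, "no feature columns found")
  for (f in feature_names) {
    assert_that(is.numeric(df[[f]]) || all(is.na(df[[f]])),
                sprintf("feature column `%s` is not numeric", f))
  }
  subject_ids <- sort(unique(ids))
  n <- length(subject_ids); p <- nrow(grid); k <- length(feature_names)
  values <- array(0, dim = c(n, p, k))
  mask <- array(FALSE, dim = c(n, p, k))
  status <- matrix(NA_integer_, nrow = n, ncol = p)
  i_idx <- match(ids, subject_ids)
  t_idx <- match(visits, grid$label)
  for (r in seq_len(nrow(df))) {
    v <- as.numeric(unlist(df[r, feature_names], use.names = FALSE))
    obs <- !is.na(v)
    values[i_idx[r], t_idx[r], obs] <- v[obs]
    mask[i_idx[r], t_idx[r], ] <- obs
    if (!is.null(status_column)) {
      status[i_idx[r], t_idx[r]] <- as.integer(df[[status_column]][r])
    }
  }
  longitudinal_cohort(values, mask, subject_ids, grid, feature_names,
                      status = if (is.null(status_column)) NULL else status)
}

#' Align a cohort to a visit grid
#'
#' Reindexes the visit axis onto `grid`: observed visits outside the grid are
#' dropped, grid visits absent from the cohort are masked unobserved, and
#' subjects observed at fewer than `min_fraction` of the grid visits are
#' removed (their ids are reported and attached as attribute `dropped`).
#' The operation is idempotent.
#'
#' @param cohort A `longitudinal_cohort`.
#' @param grid Target visit grid.
#' @param min_fraction Minimum fraction of grid visits with at least one
#'   observed cell for a subject to be retained (default 0.5).
#' @return A `longitudinal_cohort` on the new grid.
#' @export
align_time_grid <- function(cohort, grid, min_fraction = 0.5) {
  grid <- validate_visit_grid(grid)
  d <- dim(cohort$values)
  p_new <- nrow(grid)
  idx <- match(grid$label, cohort$visit_grid$label)  # NA = visit absent
  values <- array(0, dim = c(d[1], p_new, d[3]))
  mask <- array(FALSE, dim = c(d[1], p_new, d[3]))
  status <- if (is.null(cohort$status)) NULL else
    matrix(NA_integer_, nrow = d[1], ncol = p_new)
  for (t in seq_len(p_new)) {
    if (!is.na(idx[t])) {
      values[, t, ] <- cohort$values[, idx[t], ]
      mask[, t, ] <- cohort$mask[, idx[t], ]
      if (!is.null(status)) status[, t] <- cohort$status[, idx[t]]
    }
  }
  visits_observed <- apply(mask, c(1, 2), any)
  keep <- rowMeans(visits_observed) >= min_fraction
  assert_that(any(keep), "all subjects dropped by the visit-retention rule")
  dropped <- cohort$subject_ids[!keep]
  if (length(dropped) > 0) {
    rlang::inform(sprintf("align_time_grid: dropped %d subject(s) below %.0f%% visit coverage",
                          length(dropped), 100 * min_fraction))
  }
  out <- longitudinal_cohort(values[keep, , , drop = FALSE],
                             mask[keep, , , drop = FALSE],
                             cohort$subject_ids[keep], grid,
                             cohort$feature_names,
                             status = if (is.null(status)) NULL else
                               status[keep, , drop = FALSE])
  attr(out, "dropped") <- dropped
  out
}

#' Impute unobserved cells
#'
#' Default method `"knn"` fills each missing cell with the mean of that cell
#' over the `n_neighbors` subjects nearest in Euclidean distance, computed on
#' the cells the two subjects jointly observe (root mean squared difference,
#' so the distance is comparable across varying overlap). `"locf"` carries the
#' last observation forward along the visit axis (then backward for leading
#' gaps, then falls back to the cross-subject cell mean). Observed cells are
#' never altered; the returned mask is all `TRUE`.
#'
#' @param cohort A `longitudinal_cohort`.
#' @param n_neighbors Number of nearest subjects to average (default 5).
#' @param method `"knn"` (nearest-subject mean) or `"locf"`.
#' @return A fully observed `longitudinal_cohort`.
#' @export
impute_missing <- function(cohort, n_neighbors = 5, method = c("knn", "locf")) {
  method <- match.arg(method)
  d <- dim(cohort$values)
  if (all(cohort$mask)) return(cohort)
  cell_observed <- apply(cohort$mask, c(2, 3), any)
  if (!all(cell_observed)) {
    bad <- which(!cell_observed, arr.ind = TRUE)[1, ]
    rlang::abort(sprintf(
      "cell (visit %s, feature %s) is observed in no subject; cannot impute",
      cohort$visit_grid$label[bad[1]], cohort$feature_names[bad[2]]))
  }
  values <- cohort$values
  mask <- cohort$mask
  # cross-subject mean of each (visit, feature) cell over observing subjects
  vals_na <- values
  vals_na[!mask] <- NA
  cell_mean <- apply(vals_na, c(2, 3), mean, na.rm = TRUE)

  if (method == "locf") {
    for (i in seq_len(d[1])) for (f in seq_len(d[3])) {
      obs <- mask[i, , f]
      if (all(obs)) next
      if (!any(obs)) {
        values[i, , f] <- cell_mean[, f]
        next
      }
      v <- values[i, , f]
      last <- NA_real_
      for (t in seq_len(d[2])) {
        if (obs[t]) last <- v[t] else if (!is.na(last)) v[t] <- last
      }
      first_obs <- which(obs)[1]          # leading gaps: next observation back
      if (first_obs > 1) v[seq_len(first_obs - 1)] <- v[first_obs]
      values[i, , f] <- v
    }
  } else {
    flat <- flatten_rowmajor(values)
    flat_mask <- flatten_rowmajor(array(as.numeric(mask), dim = d)) > 0.5
    flat_na <- flat
    flat_na[!flat_mask] <- NA
    for (i in seq_len(d[1])) {
      if (all(flat_mask[i, ])) next
      # rms distance to every other subject on jointly observed cells
      diffs <- sweep(flat_na, 2, flat_na[i, ])
      overlap <- rowSums(!is.na(diffs))
      dist_i <- sqrt(rowSums(diffs^2, na.rm = TRUE) / pmax(overlap, 1L))
      dist_i[overlap == 0L] <- Inf
      dist_i[i] <- Inf
      ord <- order(dist_i, seq_len(d[1]))
      missing_cells <- which(!mask[i, , ] , arr.ind = TRUE)
      for (r in seq_len(nrow(missing_cells))) {
        t <- missing_cells[r, 1]; f <- missing_cells[r, 2]
        donors <- ord[mask[ord, t, f] & is.finite(dist_i[ord])]
        donors <- donors[seq_len(min(n_neighbors, length(donors)))]
        values[i, t, f] <- if (length(donors) > 0) {
          mean(values[donors, t, f])
        } else {
          cell_mean[t, f]
        }
      }
    }
  }
  longitudinal_cohort(values, NULL, cohort$subject_ids, cohort$visit_grid,
                      cohort$feature_names, status = cohort$status)
}

#' Standardize a cohort pair per (visit, feature) cell
#'
#' Z-scores every (visit, feature) cell using the mean and standard deviation
#' pooled over target and background subjects, so the contrastive subtraction
#' compares like scales. Zero-variance cells are set to 0 and flagged. The
#' returned pair carries a scaling record under `$scaling` that
#' [apply_scaling()] uses to transform held-out subjects identically.
#'
#' @param pair A fully observed `cohort_pair`.
#' @return A standardized `cohort_pair` with a `$scaling` record
#'   (fields `mean`, `sd`, `degenerate`, each p x k).
#' @export
standardize_cohorts <- function(pair) {
  assert_that(inherits(pair, "cohort_pair"), "`pair` must be a cohort_pair")
  assert_that(all(pair$target$mask) && all(pair$background$mask),
              "cohorts must be imputed (fully observed) before standardization")
  tv <- pair$target$values; bv <- pair$background$values
  n1 <- dim(tv)[1]; n2 <- dim(bv)[1]
  pooled <- array(0, dim = c(n1 + n2, dim(tv)[2:3]))
  pooled[seq_len(n1), , ] <- tv
  pooled[n1 + seq_len(n2), , ] <- bv
  cell_mean <- apply(pooled, c(2, 3), mean)
  cell_sd <- apply(pooled, c(2, 3), stats::sd)
  degenerate <- cell_sd < .Machine$double.eps^0.5
  if (any(degenerate)) {
    rlang::warn(sprintf("standardize_cohorts: %d zero-variance cell(s) set to 0",
                        sum(degenerate)))
  }
  scaling <- list(mean = cell_mean, sd = cell_sd, degenerate = degenerate,
                  visit_grid = pair$target$visit_grid,
                  feature_names = pair$target$feature_names)
  class(scaling) <- "cohort_scaling"
  cohort_pair(apply_scaling(pair$target, scaling),
              apply_scaling(pair$background, scaling),
              scaling = scaling)
}

#' Apply a stored scaling record to a cohort
#'
#' @param cohort A fully observed `longitudinal_cohort` on the same grid and
#'   feature set as the record.
#' @param scaling A scaling record from [standardize_cohorts()].
#' @return The standardized cohort (attribute `standardized` set).
#' @export
apply_scaling <- function(cohort, scaling) {
  assert_that(inherits(scaling, "cohort_scaling"), "invalid scaling record")
  assert_that(identical(cohort$feature_names, scaling$feature_names) &&
                identical(cohort$visit_grid$label, scaling$visit_grid$label),
              "cohort does not match the scaling record's grid/features")
  d <- dim(cohort$values)
  sd_safe <- ifelse(scaling$degenerate, 1, scaling$sd)
  values <- cohort$values
  for (t in seq_len(d[2])) {
    values[, t, ] <- sweep(sweep(values[, t, , drop = FALSE], 3,
                                 scaling$mean[t, ]), 3, sd_safe[t, ], "/")
    if (any(scaling$degenerate[t, ])) values[, t, scaling$degenerate[t, ]] <- 0
  }
  out <- longitudinal_cohort(values, cohort$mask, cohort$subject_ids,
                             cohort$visit_grid, cohort$feature_names,
                             status = cohort$status)
  attr(out, "standardized") <- TRUE
  out
}
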