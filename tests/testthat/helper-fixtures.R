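# Small fixtures and independent oracles shared across test files.

# Cohort from an explicit N x p x k array (months 0, 6, 12, ...).
cohort_from_array <- function(values, mask = NULL, ids = NULL) {
  d <- dim(values)
  longitudinal_cohort(
    values, mask,
    subject_ids = ids %||% sprintf("s%02d", seq_len(d[1])),
    visit_grid = visit_grid(seq(0, by = 6, length.out = d[2])),
    feature_names = sprintf("f%02d", seq_len(d[3])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random fully observed cohort pair on a shared grid.
toy_pair <- function(n1 = 6, n2 = 5, p = 3, k = 4, seed = 42) {
  withr::with_seed(seed, {
    t_vals <- array(rnorm(n1 * p * k), c(n1, p, k))
    b_vals <- array(rnorm(n2 * p * k), c(n2, p, k))
    cohort_pair(cohort_from_array(t_vals, ids = sprintf("t%02d", 1:n1)),
                cohort_from_array(b_vals, ids = sprintf("b%02d", 1:n2)))
  })
}

# Long-format CSV content for read_cohort tests.
toy_long_table <- function() {
  tibble::tibble(
    subject_id = rep(c("a", "b"), each = 2),
    visit = rep(c("m00", "m06"), times = 2),
    x1 = c(1, 2, 3, 4), x2 = c(5, 6, 7, 8), x3 = c(9, 10, 11, 12))
}

# Numeric matrix of the OR flattening (drops the id column).
flatten_or <- function(cohort) {
  as.matrix(represent_or(cohort)[, -1])
}

# --- independent oracles -----------------------------------------------------

# Explicit double-loop contrastive covariance (target side), one axis.
loop_axis_covariance <- function(values, axis) {
  d <- dim(values)
  mean_mat <- matrix(0, d[2], d[3])
  for (i in seq_len(d[1])) mean_mat <- mean_mat + values[i, , ] / d[1]
  acc <- 0
  for (i in seq_len(d[1])) {
    ci <- values[i, , ] - mean_mat
    acc <- acc + if (axis == "feature") t(ci) %*% ci else ci %*% t(ci)
  }
  acc / d[1]
}

# Recursive traversal Gini-importance oracle for a ranger tree: descends the
# recorded splits with the in-bag-weighted samples and accumulates the
# documented importance contract (literal unweighted child subtraction, clamp
# negative totals at zero, normalize).
oracle_gini_importance <- function(gf, weighted = FALSE) {
  x <- gf$x; y <- gf$y
  k <- ncol(x)
  vim <- numeric(k)
  gini <- function(w_by_class) {
    tot <- sum(w_by_class)
    if (tot == 0) return(NA_real_)
    1 - sum((w_by_class / tot)^2)
  }
  for (t in seq_len(gf$n_trees)) {
    ti <- ranger::treeInfo(gf$forest, t)
    inbag <- gf$forest$inbag.counts[[t]]
    n_root <- sum(inbag)
    recurse <- function(node, rows, w) {
      if (ti$terminal[node]) return(invisible(NULL))
      j <- ti$splitvarID[node] + 1L
      left <- rows[x[rows, j] <= ti$splitval[node]]
      right <- setdiff(rows, left)
      wl <- w[match(left, rows)]; wr <- w[match(right, rows)]
      cnt <- function(r, wts) {
        sapply(levels(y), function(cl) sum(wts[y[r] == cl]))
      }
      gq <- gini(cnt(rows, w)); gl <- gini(cnt(left, wl)); gr <- gini(cnt(right, wr))
      if (!any(is.na(c(gq, gl, gr)))) {
        vim[j] <<- vim[j] + if (weighted) {
          (sum(w) * gq - sum(wl) * gl - sum(wr) * gr) / n_root
        } else {
          gq - gl - gr
        }
      }
      recurse(ti$leftChild[node] + 1L, left, wl)
      recurse(ti$rightChild[node] + 1L, right, wr)
    }
    rows <- which(inbag > 0)
    recurse(1L, rows, inbag[rows])
  }
  vim <- pmax(vim, 0)
  vim / sum(vim)
}

# Principal angles between the column spaces of two orthonormal bases.
principal_angles <- function(a, b) {
  s <- svd(crossprod(a, b))$d
  acos(pmin(pmax(s, -1), 1))
}
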