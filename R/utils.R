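# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||%
NULL

# Deterministic 32-bit sub-seed derived from a master seed and a string salt.
derive_seed <- function(seed, salt) {
  h <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L)
}

# Evaluate `expr` under a local RNG stream, restoring global state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Row-major (visit-major) flattening of an N x p x k tensor into N x (p*k).
flatten_rowmajor <- function(values, visit_labels = NULL, feature_names = NULL) {
  d <- dim(values)
  stopifnot(length(d) == 3L)
  # aperm to N x k x p then matrix() walks features fastest within each visit
  flat <- matrix(aperm(values, c(1L, 3L, 2L)), nrow = d[1L], ncol = d[2L] * d[3L])
  if (!is.null(visit_labels) && !is.null(feature_names)) {
    colnames(flat) <- as.vector(t(outer(visit_labels, feature_names, paste, sep = ".")))
  }
  flat
}

# Inverse of flatten_rowmajor for a single subject: length p*k vector -> p x k.
unflatten_rowmajor <- function(x, p, k) {
  matrix(x, nrow = p, ncol = k, byrow = TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) rlang::abort(msg)
  invisible(TRUE)
}
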