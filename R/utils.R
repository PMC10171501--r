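# Shared numerical helpers. Edge vectorization is lexicographic over the
# upper triangle with 0-based ROI indices: (0,1), (0,2), ..., (0,m-1),
# (1,2), ... This convention is fixed package-wide and carried in
# `edge_index` tibbles alongside every edge-space object.

#' Edge index for an m-ROI network
#'
#' Enumerates the E = m(m-1)/2 unordered ROI pairs in lexicographic order
#' with 0-based indices, the order used to vectorize connectivity matrices
#' throughout the package.
#'
#' @param m Number of ROIs (>= 2).
#' @return A tibble with integer columns `i`, `j` (0-based, `i < j`).
#' @export
#' @examples
#' edge_index_pairs(4)
edge_index_pairs <- function(m) {
  stopifnot(is.numeric(m), length(m) == 1, m >= 2)
  m <- as.integer(m)
  i <- rep.int(seq_len(m - 1L) - 1L, times = (m - 1L):1L)
  j <- unlist(lapply(seq_len(m - 1L), function(a) a:(m - 1L)), use.names = FALSE)
  tibble(i = i, j = j)
}

# Linear indices into an m x m matrix selecting the upper triangle in
# lexicographic (row-major) order.
edge_linear_index <- function(m) {
  ei <- edge_index_pairs(m)
  ei$j * m + ei$i + 1L  # column-major linear index of element (i+1, j+1)
}

# Vectorize a symmetric m x m matrix to its E upper-triangle entries
# (lexicographic order).
sym_to_edge_vec <- function(mat) {
  m <- nrow(mat)
  mat[edge_linear_index(m)]
}

# Inverse of sym_to_edge_vec: rebuild the symmetric matrix (zero diagonal
# unless `diag` supplied).
edge_vec_to_sym <- function(v, m, diag = 0) {
  out <- matrix(0, m, m)
  idx <- edge_linear_index(m)
  out[idx] <- v
  out <- out + t(out)
  if (length(diag) == 1) diag <- rep(diag, m)
  diag(out) <- diag
  out
}

# Fisher z-transform with |r| clamped so the result stays finite.
fisher_z <- function(r, clamp = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clamp), clamp))
}

# Project a symmetric matrix to the nearest positive-definite matrix by
# clipping eigenvalues from below.
nearest_pd <- function(mat, eps = 1e-6) {
  es <- eigen(mat, symmetric = TRUE)
  if (all(es$values >= eps)) return(list(mat = mat, sqrt = es$vectors %*% (sqrt(es$values) * t(es$vectors))))
  lam <- pmax(es$values, eps)
  list(
    mat = es$vectors %*% (lam * t(es$vectors)),
    sqrt = es$vectors %*% (sqrt(lam) * t(es$vectors))
  )
}

# Centered moving average with edge replication, used to smooth weight
# trajectories. Width is forced odd.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  half <- (width - 1L) %/% 2L
  padded <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(padded, rep(1 / width, width), sides = 2))[(half + 1L):(half + length(x))]
}

# Deterministic per-stage seed derivation from a root seed; stays < 2^31.
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Coerce a data frame / tibble / matrix of features to a numeric matrix,
# peeling off an optional subject_id column; returns matrix with rownames.
as_feature_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  x <- as.data.frame(x)
  ids <- NULL
  if ("subject_id" %in% names(x)) {
    ids <- as.character(x$subject_id)
    x$subject_id <- NULL
  }
  bad <- !vapply(x, is.numeric, logical(1))
  if (any(bad)) {
    abort(paste0("non-numeric feature columns: ", paste(names(x)[bad], collapse = ", ")))
  }
  mat <- as.matrix(x)
  if (!is.null(ids)) rownames(mat) <- ids
  mat
}
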