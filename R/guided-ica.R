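# Group-level spatial ICA over stacked dynamic-connectivity windows and
# reference-guided subject back-reconstruction, in the spirit of
# group-information-guided ICA: group components act as anchors and each
# subject component is refined by a one-unit negentropy fixed point blended
# toward its reference.
#
# Orientation: the "samples" of the ICA are the E edges; windows are
# observations mixing K edge-space source patterns through time-varying
# weights. Sparse patterns are super-Gaussian over edges, which the logcosh
# contrast targets.

# Fixed-point symmetric FastICA on whitened data Y (K x E, rows ~ unit
# variance over edges). Returns the K x E source estimates.
fastica_symmetric <- function(Y, max_iter = 500, tol = 1e-8) {
  K <- nrow(Y); E <- ncol(Y)
  W <- matrix(rnorm(K * K), K, K)
  sym_decorrelate <- function(W) {
    es <- eigen(W %*% t(W), symmetric = TRUE)
    es$vectors %*% (1 / sqrt(pmax(es$values, 1e-12)) * t(es$vectors)) %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    U <- W %*% Y
    G <- tanh(U)
    Wn <- (G %*% t(Y)) / E - rowMeans(1 - G^2) * W
    Wn <- sym_decorrelate(Wn)
    delta <- 1 - min(abs(diag(Wn %*% t(W))))
    W <- Wn
    if (delta < tol) break
  }
  W %*% Y
}

# Normalize pattern rows to unit L2 norm and fix sign so each row's
# maximum-magnitude entry is positive.
canonicalize_patterns <- function(P) {
  nrm <- sqrt(rowSums(P^2))
  nrm[nrm == 0] <- 1
  P <- P / nrm
  for (k in seq_len(nrow(P))) {
    jmax <- which.max(abs(P[k, ]))
    if (P[k, jmax] < 0) P[k, ] <- -P[k, ]
  }
  P
}

#' Group-level ICA of dynamic connectivity
#'
#' Stacks all subjects' window-by-edge matrices, centres edges, reduces to
#' K principal dimensions, and runs fixed-point negentropy (logcosh) ICA in
#' edge space. Components are unit-norm, sign-fixed (largest-magnitude
#' loading positive) and ordered by the variance of their window weights in
#' the stacked data.
#'
#' @param dfc_list List of `dfc_series` objects (>= 2 subjects).
#' @param K Number of components (default 20).
#' @param seed Integer seed for the ICA initialization.
#' @return A `group_components` object with `patterns` (K x E),
#'   `retained_variance` from the PCA reduction, `edge_index` and
#'   `roi_labels`.
#' @export
fit_group_components <- function(dfc_list, K = 20, seed = 1L) {
  if (length(dfc_list) < 2) abort("group ICA needs at least 2 subjects.")
  # Remove each subject's mean edge vector before stacking (the usual group
  # ICA convention): between-subject offsets in static connectivity would
  # otherwise dominate the PCA over the within-subject dynamics of interest.
  X <- do.call(rbind, lapply(dfc_list, function(d) {
    sweep(d$edges, 2, colMeans(d$edges))
  }))
  E <- ncol(X)
  if (K > min(nrow(X), E)) {
    abort(sprintf("K = %d exceeds the stacked data dimensions (%d x %d).", K, nrow(X), E))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = K)
  d_all <- svd(Xc, nu = 0, nv = 0)$d
  if (d_all[K] < 1e-10 * d_all[1]) {
    abort(sprintf("rank error: stacked dFC data has rank < K = %d.", K))
  }
  Y <- t(sv$v) * sqrt(E)  # K x E, orthonormal rows scaled to unit variance

  withr::local_seed(seed)
  S <- fastica_symmetric(Y)
  P <- canonicalize_patterns(S)

  # Order components by the variance of their fitted window weights.
  wts <- tryCatch(ols_window_weights(Xc, P), error = function(e) NULL)
  if (!is.null(wts)) {
    ord <- order(apply(wts, 1, var), decreasing = TRUE)
    P <- P[ord, , drop = FALSE]
  }

  structure(
    list(patterns = P, K = K,
         retained_variance = sum(d_all[seq_len(K)]^2) / sum(d_all^2),
         edge_index = dfc_list[[1]]$edge_index,
         roi_labels = dfc_list[[1]]$roi_labels,
         edge_means = mu),
    class = "group_components"
  )
}

#' @export
print.group_components <- function(x, ...) {
  cat(sprintf("<group_components> K = %d over %d edges; PCA retained %.1f%% variance\n",
              x$K, ncol(x$patterns), 100 * x$retained_variance))
  invisible(x)
}

#' @export
#' @exportS3Method generics::glance
glance.group_components <- function(x, ...) {
  tibble(K = x$K, n_edges = ncol(x$patterns), retained_variance = x$retained_variance)
}

#' Reference-guided subject components
#'
#' For each group component k, runs a one-unit negentropy fixed point on the
#' subject's PCA-whitened dynamic connectivity, blending every update toward
#' the reference direction:
#' `w <- normalize((1 - lambda_ref) * w_ica + lambda_ref * w_ref)`,
#' initialized at `w_ref`, the projection of group pattern k onto the
#' subject's whitened subspace. `lambda_ref = 1` returns pure projections
#' (no ICA movement); `lambda_ref = 0` is unguided one-unit ICA started at
#' the reference.
#'
#' @param dfc A `dfc_series` object.
#' @param group A [fit_group_components()] object.
#' @param lambda_ref Blend weight toward the reference, in `[0, 1]`
#'   (default 0.5).
#' @param max_iter,tol Fixed-point iteration controls. Non-convergence
#'   raises a warning and flags the component, never fails silently.
#' @param n_dim Dimension of the subject's whitened space; default `NULL`
#'   uses the full numerical rank of the subject's centred dFC (capped at
#'   W - 1 and E - 1), so references lose as little as possible in the
#'   projection while the whitening stays data-dependent.
#' @return A `subject_components` object: `patterns` (K x E, unit-norm,
#'   sign-fixed), `weights` (K x W window weights via OLS),
#'   `reference_similarity` (Pearson correlation with the guiding group
#'   pattern), `converged` and `iterations` per component.
#' @export
fit_subject_components <- function(dfc, group, lambda_ref = 0.5,
                                   max_iter = 1000, tol = 1e-6, n_dim = NULL) {
  stopifnot(inherits(dfc, "dfc_series"), inherits(group, "group_components"))
  if (lambda_ref < 0 || lambda_ref > 1) abort("`lambda_ref` must be in [0, 1].")
  K <- group$K
  X <- dfc$edges
  E <- ncol(X)
  if (ncol(group$patterns) != E) abort("subject and group edge spaces differ.")
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0)
  rank <- sum(sv$d > 1e-10 * sv$d[1])
  # Never whiten onto a complete basis of edge space (n_dim = E): with a
  # complete basis the fixed-point map provably loses all dependence on the
  # subject's data and every subject would yield identical patterns.
  n_dim <- if (is.null(n_dim)) {
    min(rank, nrow(X) - 1L, E - 1L)
  } else {
    min(n_dim, rank, E - 1L)
  }
  Y <- t(sv$v[, seq_len(n_dim), drop = FALSE]) * sqrt(E)  # whitened basis

  patterns <- matrix(0, K, E)
  converged <- logical(K)
  iterations <- integer(K)
  for (k in seq_len(K)) {
    r <- drop(Y %*% group$patterns[k, ]) / E
    if (sqrt(sum(r^2)) < 1e-12) {
      warn(sprintf("component %d: reference has no support in the subject subspace.", k))
      patterns[k, ] <- group$patterns[k, ]
      next
    }
    w_ref <- r / sqrt(sum(r^2))
    w <- w_ref
    done <- FALSE
    for (it in seq_len(max_iter)) {
      u <- drop(crossprod(w, Y))
      g <- tanh(u)
      w_ica <- drop(Y %*% g) / E - mean(1 - g^2) * w
      if (sum(w_ica * w_ref) < 0) w_ica <- -w_ica
      w_new <- (1 - lambda_ref) * w_ica + lambda_ref * w_ref
      w_new <- w_new / sqrt(sum(w_new^2))
      if (abs(sum(w_new * w)) > 1 - tol) { w <- w_new; done <- TRUE; iterations[k] <- it; break }
      w <- w_new
    }
    if (!done) {
      iterations[k] <- max_iter
      warn(sprintf("component %d did not converge after %d iterations.", k, max_iter))
    }
    converged[k] <- done
    patterns[k, ] <- drop(crossprod(w, Y))
  }
  patterns <- canonicalize_patterns(patterns)
  # Guided components keep the orientation of their reference: flip any
  # pattern anti-correlated with its group anchor (the max-entry convention
  # can be inverted by edge noise).
  for (k in seq_len(K)) {
    if (suppressWarnings(cor(patterns[k, ], group$patterns[k, ])) < 0) {
      patterns[k, ] <- -patterns[k, ]
    }
  }
  ref_sim <- vapply(seq_len(K), function(k) {
    suppressWarnings(cor(patterns[k, ], group$patterns[k, ]))
  }, numeric(1))

  weights <- estimate_window_weights(dfc, patterns)

  structure(
    list(subject_id = dfc$subject_id, patterns = patterns, weights = weights,
         reference_similarity = ref_sim, converged = converged,
         iterations = iterations, lambda_ref = lambda_ref,
         edge_index = dfc$edge_index, roi_labels = dfc$roi_labels),
    class = "subject_components"
  )
}

#' @export
print.subject_components <- function(x, ...) {
  cat(sprintf("<subject_components> subject '%s': %d components x %d edges; median reference similarity %.3f\n",
              x$subject_id, nrow(x$patterns), ncol(x$patterns),
              stats::median(x$reference_similarity)))
  invisible(x)
}

#' @export
#' @exportS3Method generics::tidy
tidy.subject_components <- function(x, ...) {
  tibble(
    subject_id = x$subject_id,
    component = seq_len(nrow(x$patterns)),
    reference_similarity = x$reference_similarity,
    converged = x$converged,
    iterations = x$iterations
  )
}

# Core OLS solve shared by estimate_window_weights(): regress each window's
# edge vector on the K patterns plus an intercept.
ols_window_weights <- function(edges, patterns) {
  X <- cbind(1, t(patterns))
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) abort("collinearity error: patterns are not of full row rank.")
  coefs <- qr.coef(qr_X, t(edges))
  coefs[-1, , drop = FALSE]
}

#' Time-varying component weights by per-window OLS
#'
#' For each window, ordinary least squares of the window's edge vector on
#' the K component patterns (with intercept); the weights are the K
#' regression coefficients.
#'
#' @param dfc A `dfc_series` object.
#' @param patterns K x E pattern matrix of full row rank.
#' @return A K x W weight matrix.
#' @export
estimate_window_weights <- function(dfc, patterns) {
  stopifnot(inherits(dfc, "dfc_series"))
  ols_window_weights(dfc$edges, patterns)
}
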