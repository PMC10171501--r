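# Per-subject scalar features: one graph global-efficiency measure and one
# weight fluctuation coefficient per component (2K features, 40 at K = 20).

#' Global efficiency of a component's weighted graph
#'
#' Builds the m-node weighted graph with `w_ij = |loading_ij| / max|loading|`
#' (edges absent where the loading is zero), takes edge lengths `1 / w_ij`,
#' and returns `E_glob = mean over ordered pairs of 1 / d_ij` with
#' `1 / Inf = 0`. Max-normalization makes the measure scale-free and bounded
#' in [0, 1]; negative loadings enter through their absolute value.
#'
#' @param pattern Length-E edge loading vector (lexicographic order).
#' @param m ROI count.
#' @return Efficiency in [0, 1]. An all-zero pattern returns 0 with a
#'   warning.
#' @export
#' @examples
#' # 3-node path graph (edges 1-2 and 2-3): (1 + 1 + 1/2) / 3
#' p <- c(1, 0, 1)
#' global_efficiency(p, 3)
global_efficiency <- function(pattern, m) {
  if (!all(is.finite(pattern))) abort("`pattern` must be finite.")
  w <- abs(pattern)
  mx <- max(w)
  if (mx == 0) {
    warn("degenerate pattern: all loadings are zero; efficiency is 0.")
    return(0)
  }
  w <- w / mx
  adj <- edge_vec_to_sym(w, m)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", weighted = TRUE)
  len <- 1 / igraph::E(g)$weight
  d <- igraph::distances(g, weights = len)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (m * (m - 1))
}

#' Fluctuation coefficient of a weight trajectory
#'
#' Mean absolute frame-wise change of a component's time-varying weights:
#' `mean(|w[t+1] - w[t]|)`.
#'
#' @param weights_k Numeric trajectory of length W >= 2.
#' @return A non-negative scalar.
#' @export
#' @examples
#' fluctuation_coefficient(c(1, 2, 4))  # (1 + 2) / 2 = 1.5
fluctuation_coefficient <- function(weights_k) {
  if (length(weights_k) < 2) abort("trajectory must have at least 2 frames.")
  mean(abs(diff(weights_k)))
}

#' Feature vector of a subject's component decomposition
#'
#' Applies [global_efficiency()] to every component pattern and
#' [fluctuation_coefficient()] to every weight trajectory, yielding the
#' 2K-dimensional feature vector (`ge_IC01..ge_ICk`, `fc_IC01..fc_ICk`).
#'
#' @param sc A [fit_subject_components()] object.
#' @param m ROI count (defaults to the length of the stored ROI labels).
#' @return A one-row tibble: `subject_id` plus 2K feature columns.
#' @export
extract_feature_vector <- function(sc, m = length(sc$roi_labels)) {
  stopifnot(inherits(sc, "subject_components"))
  K <- nrow(sc$patterns)
  ge <- vapply(seq_len(K), function(k) global_efficiency(sc$patterns[k, ], m), numeric(1))
  fc <- vapply(seq_len(K), function(k) fluctuation_coefficient(sc$weights[k, ]), numeric(1))
  out <- c(ge, fc)
  names(out) <- c(sprintf("ge_IC%02d", seq_len(K)), sprintf("fc_IC%02d", seq_len(K)))
  bind_cols(tibble(subject_id = sc$subject_id), as_tibble(as.list(out)))
}

#' @importFrom dplyr bind_cols
NULL

#' Feature table for a list of subjects
#'
#' @param sc_list List of [fit_subject_components()] objects.
#' @param m ROI count.
#' @return A tibble with one row per subject and 2K feature columns.
#' @export
extract_features <- function(sc_list, m = length(sc_list[[1]]$roi_labels)) {
  bind_rows(lapply(sc_list, extract_feature_vector, m = m))
}
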