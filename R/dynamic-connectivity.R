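# Sliding-window dynamic functional connectivity in edge-vector form.
# Windows are rectangular by default; a Gaussian taper is available. "Step
# size = 1" is interpreted as one volume (one TR), the convention of the
# sliding-window dFC literature.

#' Sliding-window dynamic functional connectivity
#'
#' For each window of `L = round(window_length_s / tr)` volumes advanced by
#' `step_volumes`, computes the Pearson correlation matrix across ROIs,
#' vectorizes its upper triangle in lexicographic edge order and applies the
#' Fisher z-transform (with `|r|` clamped at `1 - 1e-7` so z stays finite).
#'
#' The number of windows is `W = floor((T - L) / step) + 1`. Setting
#' `step_volumes = T - L + 1` degenerates to a single window equal to static
#' connectivity.
#'
#' @param ts An [roi_timeseries()] object.
#' @param window_length_s Window length in seconds (default 60).
#' @param step_volumes Step between window starts, in volumes (default 1).
#' @param taper `"none"` (rectangular, default) or `"gaussian"` (Gaussian
#'   weights with sd = L/3 centred on the window).
#' @return A `dfc_series` object: `edges` (W x E Fisher-z matrix),
#'   `edge_index` (E-row tibble of 0-based ROI pairs), window bookkeeping
#'   and ROI labels.
#' @export
sliding_window_fc <- function(ts, window_length_s = 60, step_volumes = 1,
                              taper = c("none", "gaussian")) {
  stopifnot(inherits(ts, "roi_timeseries"))
  taper <- arg_match(taper)
  T_len <- nrow(ts$data)
  m <- ncol(ts$data)
  L <- as.integer(round(window_length_s / ts$tr))
  if (L < 3) abort("window length must span at least 3 volumes.")
  if (T_len < L) abort(sprintf("series has %d volumes but the window needs %d.", T_len, L))
  step <- as.integer(step_volumes)
  if (step < 1) abort("`step_volumes` must be a positive integer.")

  starts <- seq.int(1L, T_len - L + 1L, by = step)
  W <- length(starts)
  E <- m * (m - 1L) / 2L
  lin <- edge_linear_index(m)
  wts <- if (taper == "gaussian") {
    cw <- exp(-0.5 * ((seq_len(L) - (L + 1) / 2) / (L / 3))^2)
    cw / sum(cw)
  } else NULL

  edges <- matrix(NA_real_, W, E)
  for (w in seq_len(W)) {
    X <- ts$data[starts[w]:(starts[w] + L - 1L), , drop = FALSE]
    if (is.null(wts)) {
      sds <- apply(X, 2, sd)
      if (any(sds == 0)) {
        roi <- which(sds == 0)[1]
        abort(sprintf("degenerate window: subject '%s', window %d, ROI '%s' is constant.",
                      ts$subject_id, w, ts$roi_labels[roi]))
      }
      r <- cor(X)
    } else {
      mu <- colSums(X * wts)
      Xc <- sweep(X, 2, mu)
      C <- crossprod(Xc * sqrt(wts))
      s <- sqrt(diag(C))
      if (any(s == 0)) {
        roi <- which(s == 0)[1]
        abort(sprintf("degenerate window: subject '%s', window %d, ROI '%s' is constant.",
                      ts$subject_id, w, ts$roi_labels[roi]))
      }
      r <- C / tcrossprod(s)
    }
    edges[w, ] <- fisher_z(r[lin])
  }

  structure(
    list(subject_id = ts$subject_id, edges = edges,
         window_length_volumes = L, step_volumes = step,
         edge_index = edge_index_pairs(m), roi_labels = ts$roi_labels,
         tr = ts$tr),
    class = "dfc_series"
  )
}

#' @export
print.dfc_series <- function(x, ...) {
  cat(sprintf("<dfc_series> subject '%s': %d windows x %d edges (L = %d volumes, step = %d)\n",
              x$subject_id, nrow(x$edges), ncol(x$edges),
              x$window_length_volumes, x$step_volumes))
  invisible(x)
}

#' Rebuild a connectivity matrix from an edge vector
#'
#' @param v Length-E edge vector in the package's lexicographic order.
#' @param m ROI count.
#' @param roi_labels Optional dimnames.
#' @return A symmetric m x m matrix with zero diagonal.
#' @export
edge_vector_to_matrix <- function(v, m, roi_labels = NULL) {
  out <- edge_vec_to_sym(v, m)
  if (!is.null(roi_labels)) dimnames(out) <- list(roi_labels, roi_labels)
  out
}
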