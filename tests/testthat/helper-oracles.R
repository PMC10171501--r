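# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: Floyd-Warshall for shortest paths, direct
# per-window correlation, normal-equations least squares, and a literal
# per-point silhouette.

# All-pairs shortest paths by Floyd-Warshall on an m x m length matrix
# (Inf = absent edge), then weighted global efficiency.
oracle_global_efficiency <- function(pattern, m) {
  w <- abs(pattern)
  mx <- max(w)
  if (mx == 0) return(0)
  w <- w / mx
  len <- matrix(Inf, m, m)
  idx <- 1L
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      if (w[idx] > 0) len[i, j] <- len[j, i] <- 1 / w[idx]
      idx <- idx + 1L
    }
  }
  d <- len
  diag(d) <- 0
  for (k in 1:m) {
    for (i in 1:m) {
      for (j in 1:m) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (m * (m - 1))
}

# Direct per-window Pearson correlations, vectorized lexicographically.
oracle_window_correlations <- function(X, L, step) {
  T_len <- nrow(X)
  m <- ncol(X)
  starts <- seq.int(1L, T_len - L + 1L, by = step)
  t(vapply(starts, function(s) {
    r <- cor(X[s:(s + L - 1L), ])
    out <- numeric(m * (m - 1) / 2)
    idx <- 1L
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        out[idx] <- r[i, j]
        idx <- idx + 1L
      }
    }
    out
  }, numeric(m * (m - 1) / 2)))
}

# Literal per-point silhouette.
oracle_silhouette <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  labels <- as.integer(factor(labels))
  D <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in 1:n) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(D[i, labels == cl])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Greedy one-to-one matching of planted to recovered patterns by
# |correlation|; returns the matched correlations (planted order).
match_patterns <- function(planted, recovered) {
  C <- abs(stats::cor(t(planted), t(recovered)))
  rec <- numeric(nrow(planted))
  used <- integer(0)
  for (i in order(-apply(C, 1, max))) {
    j <- setdiff(order(-C[i, ]), used)[1]
    used <- c(used, j)
    rec[i] <- C[i, j]
  }
  rec
}

# Small dfc_series construction straight from a matrix of edge rows, for
# unit tests that do not need a time series behind it.
make_dfc <- function(edges, m, subject_id = "test") {
  structure(
    list(subject_id = subject_id, edges = edges,
         window_length_volumes = 30L, step_volumes = 1L,
         edge_index = edge_index_pairs(m),
         roi_labels = sprintf("ROI_%03d", seq_len(m)), tr = 2),
    class = "dfc_series"
  )
}

# Smooth random weight trajectories for constructed ICA problems.
smooth_weights <- function(K, n, seed) {
  withr::with_seed(seed, {
    t(vapply(seq_len(K), function(k) {
      w <- cumsum(rnorm(n + 20))
      w <- stats::filter(w, rep(1 / 11, 11), sides = 2)
      w <- w[!is.na(w)][seq_len(n)]
      as.numeric(scale(w))
    }, numeric(n)))
  })
}
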