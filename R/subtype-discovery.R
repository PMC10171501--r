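# Wrapper forward feature selection with k-means, repeated clustering with
# certainty-based label assignment, and quality diagnostics. k-means uses
# plain Lloyd iterations with centers initialized at randomly chosen data
# points: the run-to-run variability this preserves is exactly what the
# certainty measure quantifies.

# One Lloyd k-means run with random point initialization; retries on the
# (rare) empty-cluster failure. `n_start > 1` keeps the best of several
# random initializations by within-cluster sum of squares.
kmeans_run <- function(X, k, max_retries = 20, n_start = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  one <- function() {
    for (try in seq_len(max_retries)) {
      centers <- X[sample.int(n, k), , drop = FALSE]
      if (anyDuplicated(centers) > 0) next
      res <- tryCatch(
        suppressWarnings(kmeans(X, centers = centers, iter.max = 100, algorithm = "Lloyd")),
        error = function(e) NULL
      )
      if (!is.null(res)) return(res)
    }
    abort("k-means failed: could not find a valid initialization (degenerate data?).")
  }
  best <- one()
  if (n_start > 1) {
    for (s in seq_len(n_start - 1L)) {
      cand <- one()
      if (cand$tot.withinss < best$tot.withinss) best <- cand
    }
  }
  best
}

# Mean silhouette from a precomputed distance matrix (squared distances are
# accumulated feature-wise by the forward selection, so this takes plain
# Euclidean distances).
silhouette_from_dist <- function(D, labels) {
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) abort("silhouette is undefined for a single cluster.")
  n <- length(labels)
  sizes <- tabulate(labels, k)
  # mean distance from each point to each cluster
  agg <- matrix(0, n, k)
  for (cl in seq_len(k)) {
    agg[, cl] <- rowSums(D[, labels == cl, drop = FALSE])
  }
  s <- numeric(n)
  for (i in seq_len(n)) {
    cl <- labels[i]
    if (sizes[cl] == 1) { s[i] <- 0; next }
    a <- agg[i, cl] / (sizes[cl] - 1)
    b <- min(agg[i, -cl] / sizes[-cl])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Mean silhouette index
#'
#' Mean over points of `(b - a) / max(a, b)` with Euclidean distances, where
#' `a` is the mean intra-cluster distance and `b` the mean distance to the
#' nearest other cluster. Members of singleton clusters contribute 0.
#'
#' @param X N x F data matrix (or data frame with an optional `subject_id`).
#' @param labels Cluster labels, at least two distinct values.
#' @return The mean silhouette in [-1, 1].
#' @export
silhouette_index <- function(X, labels) {
  X <- as_feature_matrix(X)
  D <- as.matrix(dist(X))
  silhouette_from_dist(D, labels)
}

#' Wrapper forward feature selection with k-means
#'
#' Repeated greedy forward selection in the stability-selection style: each
#' run draws a random subject subsample (`subsample` fraction, without
#' replacement), starts from the empty feature set and, at every step, adds
#' the feature whose inclusion maximizes the mean silhouette of a fresh
#' k-means partition on the selected set, stopping when no candidate
#' improves the criterion by more than `min_improve`. Selection frequencies
#' across runs identify the informative features (frequency > `threshold`).
#'
#' Two safeguards make the procedure well-behaved. First, k-means silhouette
#' has a high null baseline (splitting even pure 1-D Gaussian noise scores
#' ~0.6), so the first feature is only accepted if it beats the best
#' silhouette obtained on a same-sized matrix of Gaussian reference draws (a
#' per-run parametric null in the spirit of the gap statistic) by
#' `min_improve`. Second, the mean
#' silhouette is essentially invariant to adding a redundant informative
#' feature but drops when a noise feature is added, so after the first
#' acceptance the run keeps adding the best candidate while the criterion
#' stays within `degrade_tol` of its running maximum. Together with
#' subsampling, this lets equally informative features accumulate high
#' frequencies while noise features spread their occasional wins across
#' runs.
#'
#' @param z_matrix N x F deviation matrix (matrix or tibble; an optional
#'   `subject_id` column is dropped).
#' @param k Number of clusters (default 2).
#' @param runs Number of repeated runs (default 100).
#' @param threshold Informative-feature frequency threshold (default 0.8).
#' @param seed Integer seed; each run draws a fresh subsample and fresh
#'   random k-means initializations from the seeded stream.
#' @param min_improve Margin by which the first feature must beat the
#'   permutation-null reference (default 1e-4).
#' @param subsample Fraction of subjects used per run (default 0.8; 1
#'   disables subsampling).
#' @param degrade_tol Largest tolerated criterion drop when adding a
#'   further feature (default 0.04).
#' @return A `selection_result`: `frequencies` tibble, `informative_features`
#'   (frequency strictly above the threshold), `runs`, `threshold` and the
#'   per-run `criterion_trace`.
#' @export
forward_select_features <- function(z_matrix, k = 2, runs = 100,
                                    threshold = 0.8, seed = 1L,
                                    min_improve = 1e-4, subsample = 0.8,
                                    degrade_tol = 0.04) {
  X <- as_feature_matrix(z_matrix)
  n <- nrow(X); F_n <- ncol(X)
  if (n <= k) abort("need more subjects than clusters.")
  if (F_n < 1 || runs < 1) abort("need at least one feature and one run.")
  if (subsample <= 0 || subsample > 1) abort("`subsample` must be in (0, 1].")
  feat_names <- colnames(X) %||% sprintf("feature_%02d", seq_len(F_n))
  colnames(X) <- feat_names

  # Per-feature pairwise squared differences, accumulated as features enter
  # the selected set (Euclidean distance over a feature set = sqrt of the
  # sum of its per-feature squared difference matrices).
  d2 <- lapply(seq_len(F_n), function(f) {
    df <- outer(X[, f], X[, f], `-`)
    df * df
  })

  n_sub <- max(k + 1L, ceiling(subsample * n))
  withr::local_seed(seed)
  counts <- numeric(F_n)
  trace <- vector("list", runs)
  # Single-feature criterion of one column, used both for the real data and
  # for the parametric null reference.
  one_feature_crit <- function(col) {
    km <- kmeans_run(matrix(col, ncol = 1), k, n_start = 3)
    D <- abs(outer(col, col, `-`))
    silhouette_from_dist(D, km$cluster)
  }

  for (r in seq_len(runs)) {
    idx <- if (n_sub < n) sort(sample.int(n, n_sub)) else seq_len(n)
    # Parametric null reference: best single-feature silhouette across F
    # unimodal Gaussian draws of the subsample size (silhouette is scale
    # invariant, so standard normal draws suffice).
    null_crit <- max(vapply(seq_len(F_n), function(f) {
      one_feature_crit(rnorm(length(idx)))
    }, numeric(1)))

    selected <- integer(0)
    acc <- matrix(0, length(idx), length(idx))
    best_crit <- -Inf
    crit_path <- numeric(0)
    repeat {
      cand <- setdiff(seq_len(F_n), selected)
      if (length(cand) == 0) break
      cand_crit <- rep(-Inf, length(cand))
      for (ci in seq_along(cand)) {
        f <- cand[ci]
        cols <- c(selected, f)
        km <- kmeans_run(X[idx, cols, drop = FALSE], k, n_start = 3)
        D <- sqrt(acc + d2[[f]][idx, idx])
        cand_crit[ci] <- silhouette_from_dist(D, km$cluster)
      }
      best_ci <- which.max(cand_crit)  # ties: lowest feature index wins
      ok <- if (length(selected) == 0) {
        cand_crit[best_ci] > null_crit + min_improve
      } else {
        cand_crit[best_ci] > best_crit - degrade_tol
      }
      if (!ok) break
      f <- cand[best_ci]
      selected <- c(selected, f)
      acc <- acc + d2[[f]][idx, idx]
      best_crit <- max(best_crit, cand_crit[best_ci])
      crit_path <- c(crit_path, cand_crit[best_ci])
    }
    counts[selected] <- counts[selected] + 1
    trace[[r]] <- tibble(step = seq_along(selected),
                         feature = feat_names[selected],
                         criterion = crit_path)
  }

  freqs <- counts / runs
  structure(
    list(frequencies = tibble(feature = feat_names, frequency = freqs),
         informative_features = feat_names[freqs > threshold],
         runs = runs, threshold = threshold, k = k,
         criterion_trace = trace),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d runs, k = %d: %d/%d features above frequency %.2f\n",
              x$runs, x$k, length(x$informative_features),
              nrow(x$frequencies), x$threshold))
  invisible(x)
}

#' @export
#' @exportS3Method generics::tidy
tidy.selection_result <- function(x, ...) {
  mutate(x$frequencies, informative = .data$frequency > x$threshold)
}

# Align labels of one run to a reference labelling by the permutation of
# cluster ids maximizing agreement (exhaustive for small k).
align_labels <- function(labels, ref, k) {
  if (k > 8) abort("label alignment supports k <= 8.")
  perms <- permutations_of(k)
  best <- labels
  best_agree <- -1L
  for (p in perms) {
    cand <- p[labels]
    agree <- sum(cand == ref)
    if (agree > best_agree) { best_agree <- agree; best <- cand }
  }
  best
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  sub <- permutations_of(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

#' Repeated k-means clustering with certainty-based labels
#'
#' Runs `runs` independent Lloyd k-means partitions with random point
#' initialization, aligns every run to the first by the best cluster-id
#' permutation, and assigns each subject its modal label. The certainty of
#' subject i is `max_label n_i(label) / runs`; subjects below
#' `certainty_threshold` are flagged excluded. Diagnostics: mean silhouette
#' of the retained subjects under the final labels, center instability
#' (mean distance of per-run centers from their across-run mean), and mean
#' stability (mean certainty of retained subjects).
#'
#' @param z_matrix N x F matrix restricted to the informative features
#'   (matrix or tibble; optional `subject_id` column used for output ids).
#' @param k Number of clusters (default 2).
#' @param runs Repeated runs (default 100).
#' @param certainty_threshold Exclusion threshold on certainty (default 0.6).
#' @param seed Integer seed.
#' @return A `cluster_ensemble` object; see [tidy.cluster_ensemble()] and
#'   [glance.cluster_ensemble()].
#' @export
cluster_ensemble <- function(z_matrix, k = 2, runs = 100,
                             certainty_threshold = 0.6, seed = 1L) {
  X <- as_feature_matrix(z_matrix)
  n <- nrow(X)
  if (n <= k) abort("need more subjects than clusters.")
  ids <- rownames(X) %||% sprintf("subject_%03d", seq_len(n))

  withr::local_seed(seed)
  labels_per_run <- matrix(NA_integer_, runs, n)
  centers_per_run <- array(NA_real_, c(runs, k, ncol(X)))
  for (r in seq_len(runs)) {
    km <- kmeans_run(X, k)
    lab <- km$cluster
    if (r > 1) lab <- align_labels(lab, labels_per_run[1, ], k)
    labels_per_run[r, ] <- lab
    for (cl in seq_len(k)) {
      centers_per_run[r, cl, ] <- colMeans(X[lab == cl, , drop = FALSE])
    }
  }

  cert <- certainty_from_labels(labels_per_run, k)
  certainty <- cert$certainty
  final <- cert$final_label
  retained <- certainty >= certainty_threshold

  sil <- if (length(unique(final[retained])) >= 2) {
    silhouette_index(X[retained, , drop = FALSE], final[retained])
  } else NA_real_

  center_mean <- apply(centers_per_run, c(2, 3), mean)
  center_instability <- mean(vapply(seq_len(runs), function(r) {
    sum(sqrt(rowSums((centers_per_run[r, , , drop = FALSE][1, , ] - center_mean)^2)))
  }, numeric(1)))

  structure(
    list(assignments = tibble(subject_id = ids, final_label = final,
                              certainty = certainty, retained = retained),
         labels_per_run = labels_per_run, k = k, runs = runs,
         certainty_threshold = certainty_threshold,
         silhouette = sil, center_instability = center_instability,
         mean_stability = mean(certainty[retained]),
         data = X),
    class = "cluster_ensemble"
  )
}

#' @export
print.cluster_ensemble <- function(x, ...) {
  sizes <- table(x$assignments$final_label[x$assignments$retained])
  cat(sprintf("<cluster_ensemble> k = %d, %d runs: sizes %s; silhouette %.3f, instability %.3f, stability %.3f\n",
              x$k, x$runs, paste(sizes, collapse = "/"),
              x$silhouette, x$center_instability, x$mean_stability))
  if (any(!x$assignments$retained)) {
    cat(sprintf("  %d subject(s) excluded with certainty < %.2f\n",
                sum(!x$assignments$retained), x$certainty_threshold))
  }
  invisible(x)
}

#' Per-subject cluster assignments
#'
#' @param x A [cluster_ensemble()] object.
#' @param ... Unused.
#' @return Tibble with `subject_id`, `final_label`, `certainty`, `retained`.
#' @export
#' @exportS3Method generics::tidy
tidy.cluster_ensemble <- function(x, ...) x$assignments

#' Clustering quality summary
#'
#' @param x A [cluster_ensemble()] object.
#' @param ... Unused.
#' @return One-row tibble with the silhouette, center instability, mean
#'   stability, and counts.
#' @export
#' @exportS3Method generics::glance
glance.cluster_ensemble <- function(x, ...) {
  tibble(k = x$k, runs = x$runs,
         n = nrow(x$assignments), n_retained = sum(x$assignments$retained),
         silhouette = x$silhouette,
         center_instability = x$center_instability,
         mean_stability = x$mean_stability)
}

#' Certainty and modal label from repeated clustering runs
#'
#' For each subject, certainty is the fraction of runs assigning its most
#' frequent (aligned) label, `max_i n_i / n`; the final label is that
#' argmax, with ties broken toward the lowest label index.
#'
#' @param labels_per_run R x N matrix of aligned cluster labels (one row
#'   per run).
#' @param k Number of clusters (defaults to the largest label present).
#' @return A list with numeric `certainty` (in `[1/k, 1]`) and integer
#'   `final_label`, each of length N.
#' @export
#' @examples
#' runs <- rbind(matrix(1, 97, 1), matrix(2, 3, 1))
#' certainty_from_labels(runs)  # certainty 0.97, label 1
certainty_from_labels <- function(labels_per_run, k = max(labels_per_run)) {
  labels_per_run <- as.matrix(labels_per_run)
  runs <- nrow(labels_per_run)
  n <- ncol(labels_per_run)
  count_mat <- vapply(seq_len(k), function(cl) colSums(labels_per_run == cl),
                      numeric(n))
  count_mat <- matrix(count_mat, nrow = n)
  list(certainty = apply(count_mat, 1, max) / runs,
       final_label = apply(count_mat, 1, which.max))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement, used to compare recovered subtypes against
#' planted labels.
#'
#' @param a,b Two label vectors of equal length.
#' @return The ARI (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
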