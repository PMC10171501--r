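# Silhouette, certainty/label rules, repeated clustering, and the wrapper
# feature selection.

test_that("silhouette matches a brute-force per-point computation", {
  withr::local_seed(71)
  X <- matrix(rnorm(30 * 3), 30, 3)
  labels <- sample(1:3, 30, TRUE)
  expect_equal(silhouette_index(X, labels), oracle_silhouette(X, labels),
               tolerance = 1e-12)
  # two tight far-apart pairs
  Y <- rbind(c(0, 0), c(0.01, 0), c(10, 0), c(10.01, 0))
  expect_gt(silhouette_index(Y, c(1, 1, 2, 2)), 0.99)
  expect_error(silhouette_index(X, rep(1, 30)), "single cluster")
})

test_that("random labels on overlapping clouds give near-zero silhouette", {
  withr::local_seed(72)
  X <- matrix(rnorm(400 * 2), 400, 2)
  labels <- sample(1:2, 400, TRUE)
  expect_lt(abs(silhouette_index(X, labels)), 0.05)
})

test_that("certainty is max n_i / n with argmax labeling and low-index ties", {
  runs <- rbind(matrix(1L, 97, 1), matrix(2L, 3, 1))
  cert <- certainty_from_labels(runs)
  expect_equal(cert$certainty, 0.97)
  expect_equal(cert$final_label, 1L)
  # exact tie: lowest label index wins
  tie <- matrix(c(rep(1L, 50), rep(2L, 50)), ncol = 1)
  expect_equal(certainty_from_labels(tie)$final_label, 1L)
  expect_equal(certainty_from_labels(tie)$certainty, 0.5)
})

test_that("well-separated blobs cluster with certainty 1 and full recovery", {
  withr::local_seed(73)
  X <- rbind(matrix(rnorm(40 * 2, 0), 40, 2), matrix(rnorm(40 * 2, 10), 40, 2))
  truth <- rep(1:2, each = 40)
  ens <- cluster_ensemble(X, k = 2, runs = 50, seed = 1)
  expect_true(all(ens$assignments$certainty == 1))
  expect_equal(adjusted_rand_index(ens$assignments$final_label, truth), 1)
  expect_gt(ens$silhouette, 0.8)
  expect_equal(ens$mean_stability, 1)
  # certainty is invariant to a global relabeling across seeds
  ens2 <- cluster_ensemble(X, k = 2, runs = 50, seed = 99)
  expect_equal(ens2$assignments$certainty, ens$assignments$certainty)
  expect_equal(adjusted_rand_index(ens2$assignments$final_label,
                                   ens$assignments$final_label), 1)
})

test_that("low-certainty subjects are flagged for exclusion", {
  withr::local_seed(74)
  # two blobs plus one point exactly between them
  X <- rbind(matrix(rnorm(30, sd = 0.2), 15, 2),
             matrix(rnorm(30, mean = 4, sd = 0.2), 15, 2),
             c(2, 2))
  ens <- cluster_ensemble(X, k = 2, runs = 100, certainty_threshold = 0.9,
                          seed = 5)
  expect_true(all(ens$assignments$retained[1:30]))
  expect_equal(glance(ens)$n_retained, sum(ens$assignments$certainty >= 0.9))
})

test_that("adjusted Rand index behaves at its anchors", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
})

test_that("a single perfectly separating feature is always selected", {
  withr::local_seed(75)
  X <- matrix(c(rnorm(40), rnorm(40) + 8), ncol = 1)
  sel <- forward_select_features(X, k = 2, runs = 30, seed = 6)
  expect_equal(sel$frequencies$frequency, 1)
  expect_equal(sel$informative_features, "feature_01")
})

test_that("selection frequencies are reproducible under a fixed seed", {
  withr::local_seed(76)
  X <- matrix(rnorm(60 * 6), 60, 6)
  X[1:20, 1] <- X[1:20, 1] + 5
  a <- forward_select_features(X, k = 2, runs = 20, seed = 7)
  b <- forward_select_features(X, k = 2, runs = 20, seed = 7)
  expect_identical(a$frequencies, b$frequencies)
  expect_error(forward_select_features(X[1:2, ], k = 2, runs = 5), "more subjects")
})
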