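# Graph global efficiency and weight fluctuation coefficients.

test_that("global efficiency matches hand-computed small graphs", {
  # 3-node path (edges 1-2, 2-3, unit weights): d = 1, 1, 2
  p_path <- c(1, 0, 1)  # lexicographic edges (1,2), (1,3), (2,3)
  expect_equal(global_efficiency(p_path, 3), (1 + 1 + 1 / 2) / 3,
               tolerance = 1e-12)
  # complete graph with equal loadings: all distances 1 after normalization
  m <- 6
  p_complete <- rep(0.4, m * (m - 1) / 2)
  expect_equal(global_efficiency(p_complete, m), 1, tolerance = 1e-12)
  # all-zero pattern: 0 with a warning
  expect_warning(z <- global_efficiency(rep(0, 10), 5), "degenerate")
  expect_equal(z, 0)
})

test_that("global efficiency equals the Floyd-Warshall oracle on random graphs", {
  withr::local_seed(17)
  for (i in 1:25) {
    m <- sample(4:12, 1)
    E <- m * (m - 1) / 2
    p <- numeric(E)
    keep <- runif(E) < 0.4
    p[keep] <- rnorm(sum(keep))
    if (!any(keep)) p[1] <- 1
    expect_equal(global_efficiency(p, m), oracle_global_efficiency(p, m),
                 tolerance = 1e-10)
  }
})

test_that("global efficiency is scale-free and permutation-equivariant", {
  withr::local_seed(23)
  m <- 8
  p <- rnorm(m * (m - 1) / 2) * rbinom(m * (m - 1) / 2, 1, 0.5)
  expect_equal(global_efficiency(5 * p, m), global_efficiency(p, m),
               tolerance = 1e-12)
  # relabeling ROIs leaves the (label-free) efficiency unchanged
  perm <- sample(m)
  M <- edge_vector_to_matrix(p, m)
  p_perm <- dfcsubtype:::sym_to_edge_vec(M[perm, perm])
  expect_equal(global_efficiency(p_perm, m), global_efficiency(p, m),
               tolerance = 1e-12)
})

test_that("fluctuation coefficient is the mean absolute first difference", {
  expect_equal(fluctuation_coefficient(c(1, 2, 4)), 1.5)
  expect_equal(fluctuation_coefficient(rep(3.7, 50)), 0)
  withr::local_seed(4)
  w <- rnorm(500)
  expect_equal(fluctuation_coefficient(w), mean(abs(diff(w))), tolerance = 1e-12)
  expect_error(fluctuation_coefficient(1), "2 frames")
  # invariant to level shifts, linear in scale
  expect_equal(fluctuation_coefficient(w + 100), fluctuation_coefficient(w))
  expect_equal(fluctuation_coefficient(3 * w), 3 * fluctuation_coefficient(w))
})

test_that("feature vectors have 2K named entries with degenerate handling", {
  withr::local_seed(9)
  m <- 10
  E <- m * (m - 1) / 2
  K <- 4
  sc <- structure(
    list(subject_id = "s", patterns = matrix(rnorm(K * E), K, E),
         weights = matrix(rnorm(K * 20), K, 20),
         roi_labels = sprintf("ROI_%03d", 1:m)),
    class = "subject_components"
  )
  fv <- extract_feature_vector(sc)
  expect_equal(ncol(fv), 2 * K + 1)
  expect_equal(names(fv)[-1],
               c(sprintf("ge_IC%02d", 1:K), sprintf("fc_IC%02d", 1:K)))
  expect_true(all(as.numeric(fv[1, sprintf("ge_IC%02d", 1:K)]) >= 0))
  expect_true(all(as.numeric(fv[1, sprintf("ge_IC%02d", 1:K)]) <= 1))

  # all-zero pattern and constant weights give the (0, 0) pair
  sc$patterns[2, ] <- 0
  sc$weights[2, ] <- 1
  fv2 <- suppressWarnings(extract_feature_vector(sc))
  expect_equal(fv2$ge_IC02, 0)
  expect_equal(fv2$fc_IC02, 0)

  # pattern rescaling leaves efficiency features unchanged
  sc3 <- sc
  sc3$patterns[1, ] <- 5 * sc3$patterns[1, ]
  fv3 <- suppressWarnings(extract_feature_vector(sc3))
  expect_equal(fv3$ge_IC01, fv2$ge_IC01, tolerance = 1e-12)
})
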