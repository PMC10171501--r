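# Group ICA and guided subject back-reconstruction: identifiable noiseless
# cases, determinism, the pure-reference limit, window-weight OLS oracles,
# and nested-model reconstruction error.

# Build an exactly identifiable problem: sparse orthogonal patterns mixed
# by smooth weights, split across two "subjects".
make_identifiable <- function(K = 3, m = 10, n = 120, seed = 21) {
  E <- m * (m - 1) / 2
  withr::with_seed(seed, {
    P <- matrix(0, K, E)
    blocks <- split(sample(E), rep(seq_len(K), length.out = E))
    for (k in seq_len(K)) {
      sup <- blocks[[k]][seq_len(12)]
      P[k, sup] <- runif(12, 0.5, 1) * sample(c(-1, 1), 12, TRUE)
    }
  })
  W <- smooth_weights(K, n, seed + 1)
  X <- t(W) %*% P
  list(patterns = P, weights = W, X = X, m = m, E = E)
}

test_that("noiseless orthogonal patterns are recovered up to permutation/sign", {
  prob <- make_identifiable()
  dfc <- list(make_dfc(prob$X[1:60, ], prob$m, "a"),
              make_dfc(prob$X[61:120, ], prob$m, "b"))
  gc <- fit_group_components(dfc, K = 3, seed = 1)
  matched <- match_patterns(prob$patterns, gc$patterns)
  expect_true(all(matched >= 0.999))
  # unit norm and sign convention
  expect_equal(rowSums(gc$patterns^2), rep(1, 3), tolerance = 1e-10)
  for (k in 1:3) {
    expect_gt(gc$patterns[k, which.max(abs(gc$patterns[k, ]))], 0)
  }
})

test_that("group ICA is deterministic under a fixed seed and checks rank", {
  prob <- make_identifiable(seed = 33)
  dfc <- list(make_dfc(prob$X[1:60, ], prob$m), make_dfc(prob$X[61:120, ], prob$m))
  a <- fit_group_components(dfc, K = 3, seed = 5)
  b <- fit_group_components(dfc, K = 3, seed = 5)
  expect_identical(a$patterns, b$patterns)
  # data of rank 3 cannot support K = 10
  expect_error(fit_group_components(dfc, K = 10, seed = 1), "rank")
  expect_error(fit_group_components(dfc[1], K = 2), "2 subjects")
})

test_that("lambda_ref = 1 returns the pure reference projection", {
  prob <- make_identifiable(seed = 8)
  dfc <- list(make_dfc(prob$X[1:60, ], prob$m), make_dfc(prob$X[61:120, ], prob$m))
  gc <- fit_group_components(dfc, K = 3, seed = 2)
  subj <- make_dfc(prob$X[1:60, ], prob$m, "s")
  sc <- fit_subject_components(subj, gc, lambda_ref = 1)
  # oracle: project each group pattern onto the span of the centred data's
  # right singular vectors, normalize, fix sign
  Xc <- sweep(subj$edges, 2, colMeans(subj$edges))
  sv <- svd(Xc, nu = 0)
  r <- sum(sv$d > 1e-10 * sv$d[1])
  V <- sv$v[, seq_len(r), drop = FALSE]
  for (k in 1:3) {
    proj <- V %*% crossprod(V, gc$patterns[k, ])
    expect_gt(abs(cor(sc$patterns[k, ], drop(proj))), 0.999)
  }
})

test_that("subjects generated from the group patterns are self-consistent", {
  prob <- make_identifiable(seed = 13)
  dfc <- list(make_dfc(prob$X[1:60, ], prob$m), make_dfc(prob$X[61:120, ], prob$m))
  gc <- fit_group_components(dfc, K = 3, seed = 3)
  sc <- fit_subject_components(make_dfc(prob$X, prob$m), gc)
  expect_true(all(sc$reference_similarity >= 0.999))
  expect_true(all(sc$converged))
})

test_that("guided fits track planted subject-specific perturbations", {
  # m chosen so the edge space (E = 190) exceeds the window count and the
  # subject whitening truncates (data-dependent subspace)
  prob <- make_identifiable(K = 4, m = 20, n = 160, seed = 40)
  dfc <- list(make_dfc(prob$X[1:80, ], prob$m), make_dfc(prob$X[81:160, ], prob$m))
  gc <- fit_group_components(dfc, K = 4, seed = 4)
  # subject whose true patterns carry small sparse deltas
  withr::local_seed(41)
  P_sub <- prob$patterns
  for (k in 1:4) {
    idx <- sample(prob$E, 6)
    P_sub[k, idx] <- P_sub[k, idx] + rnorm(6, 0, 0.25)
  }
  W <- smooth_weights(4, 150, 42)
  X_sub <- t(W) %*% P_sub + matrix(rnorm(150 * prob$E, 0, 0.01), 150)
  sc <- fit_subject_components(make_dfc(X_sub, prob$m), gc)
  # recovered patterns must be closer to the perturbed truth than the group
  # patterns are, for most components
  P_subn <- P_sub / sqrt(rowSums(P_sub^2))
  closer <- vapply(1:4, function(k) {
    ref <- gc$patterns[k, ]
    truth_k <- P_subn[which.max(abs(cor(t(prob$patterns), ref))), ]
    abs(cor(sc$patterns[k, ], truth_k)) > abs(cor(ref, truth_k))
  }, logical(1))
  expect_gte(mean(closer), 0.8)
})

test_that("window weights solve the stated least-squares problem", {
  withr::local_seed(50)
  m <- 8
  E <- m * (m - 1) / 2
  P <- matrix(rnorm(2 * E), 2, E)
  # exact linear recovery with an intercept
  edges <- matrix(rep(2 * P[1, ] - 1 * P[2, ] + 7, 5), 5, byrow = TRUE)
  w <- estimate_window_weights(make_dfc(edges, m), P)
  expect_equal(unname(w[, 1]), c(2, -1), tolerance = 1e-10)

  # orthonormal patterns: OLS equals projection of the centred window
  Q <- qr.Q(qr(matrix(rnorm(E * 3), E, 3)))
  Po <- t(Q)
  X <- matrix(rnorm(6 * E), 6, E)
  w2 <- estimate_window_weights(make_dfc(X, m), Po)
  for (i in 1:6) {
    centred <- X[i, ] - mean(X[i, ]) * 0  # intercept handles the mean
    fitted <- lm(X[i, ] ~ t(Po))
    expect_equal(unname(w2[, i]), unname(coef(fitted)[-1]), tolerance = 1e-10)
  }

  # random K = 4 problem against an explicit normal-equations solve
  P4 <- matrix(rnorm(4 * E), 4, E)
  X4 <- matrix(rnorm(10 * E), 10, E)
  w4 <- estimate_window_weights(make_dfc(X4, m), P4)
  D <- cbind(1, t(P4))
  oracle <- solve(crossprod(D), crossprod(D, t(X4)))[-1, ]
  expect_equal(w4, oracle, tolerance = 1e-10)

  # rank-deficient patterns are rejected
  P_bad <- rbind(P[1, ], P[1, ])
  expect_error(estimate_window_weights(make_dfc(X, m), P_bad), "collinearity")
})

test_that("reconstruction error is non-increasing in K on nested fits", {
  prob <- make_identifiable(K = 4, m = 12, n = 160, seed = 60)
  X <- prob$X + matrix(rnorm(length(prob$X), 0, 0.05), nrow(prob$X))
  dfc <- list(make_dfc(X[1:80, ], prob$m), make_dfc(X[81:160, ], prob$m))
  errs <- vapply(1:4, function(K) {
    gc <- fit_group_components(dfc, K = K, seed = 7)
    w <- estimate_window_weights(make_dfc(X, prob$m), gc$patterns)
    recon <- t(w) %*% gc$patterns
    Xc <- sweep(X, 2, colMeans(X))
    sum((Xc - sweep(recon, 2, colMeans(recon)))^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})
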