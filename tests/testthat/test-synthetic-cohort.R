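# Generator: determinism, feasibility bounds, near-orthogonality of the
# planted bank, manifest invariants, and the noiseless sliding-window limit.

test_that("ground truth is reproducible and respects the rank bound", {
  a <- generate_ground_truth(K_true = 5, m = 20, sparsity = 0.1, seed = 7)
  b <- generate_ground_truth(K_true = 5, m = 20, sparsity = 0.1, seed = 7)
  expect_identical(a, b)
  expect_error(generate_ground_truth(K_true = 200, m = 10), "infeasible rank")
  expect_error(generate_ground_truth(K_true = 3, m = 10, sparsity = 1.2), "sparsity")
})

test_that("planted patterns are pairwise near-orthogonal", {
  gt <- generate_ground_truth(K_true = 5, m = 20, sparsity = 0.1, seed = 7)
  for (i in 1:4) {
    for (j in (i + 1):5) {
      cosine <- sum(gt$patterns[i, ] * gt$patterns[j, ]) /
        sqrt(sum(gt$patterns[i, ]^2) * sum(gt$patterns[j, ]^2))
      expect_lt(abs(cosine), 0.3)
    }
  }
})

test_that("cohort manifest has the stated sizes, ranges and rounding", {
  gt <- generate_ground_truth(K_true = 3, m = 10, seed = 2)
  coh <- generate_cohort(gt, n_patients = 91, n_controls_base = 91,
                         n_controls_ica = 125, T_volumes = 40, tr = 2, seed = 3)
  man <- coh$manifest
  expect_equal(nrow(man), 307)
  expect_length(coh$series, 307)
  expect_true(all(vapply(coh$series, function(s) all(dim(s) == c(40, 10)), logical(1))))
  expect_true(all(man$age >= 18 & man$age <= 50))
  expect_true(all(is.na(man$illness_duration) == (man$group != "patient")))
  expect_true(all(man$illness_duration[man$group == "patient"] >= 0))
  # deterministic rounding of the 16% subtype-I proportion: round(.16 * 91) = 15
  expect_equal(sum(man$subtype == "I", na.rm = TRUE), 15)
  expect_equal(sum(man$subtype == "II", na.rm = TRUE), 76)
  expect_error(generate_cohort(gt, 2, 0, 0, T_volumes = 0), "positive")
})

test_that("cohort generation is reproducible under a fixed seed", {
  gt <- generate_ground_truth(K_true = 3, m = 8, seed = 5)
  a <- generate_cohort(gt, 3, 2, 2, T_volumes = 60, tr = 2, seed = 9)
  b <- generate_cohort(gt, 3, 2, 2, T_volumes = 60, tr = 2, seed = 9)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$series[[1]]$data, b$series[[1]]$data)
  expect_identical(a$truth$subject_params, b$truth$subject_params)
})

test_that("weight trajectories are smooth by construction", {
  gt <- generate_ground_truth(K_true = 4, m = 10, seed = 1)
  coh <- generate_cohort(gt, 2, 0, 0, T_volumes = 210, tr = 2, seed = 1)
  for (W in coh$truth$weight_trajectories) {
    ac1 <- apply(W, 1, function(w) cor(w[-1], w[-length(w)]))
    expect_true(all(ac1 > 0.5))
  }
})

test_that("noiseless constant-weight windows equal the analytic correlation", {
  gt <- generate_ground_truth(K_true = 1, m = 5, sparsity = 0.3, seed = 4)
  coh <- generate_cohort(gt, 0, 2, 0, T_volumes = 210, tr = 2, noise_sd = 0,
                         seed = 4, weight_amplitude = 0)
  sid <- coh$manifest$subject_id[1]
  delta <- coh$truth$subject_params$delta[coh$truth$subject_params$subject_id == sid]
  A <- dfcsubtype:::edge_vec_to_sym(gt$patterns[1, ] + delta * gt$densifiers[1, ], 5)
  Sigma <- diag(5) + 0.6 * A
  analytic_r <- stats::cov2cor(dfcsubtype:::nearest_pd(Sigma)$mat)
  dfc <- sliding_window_fc(coh$series[[sid]], window_length_s = 60, step_volumes = 1)
  r_hat <- tanh(dfc$edges)
  analytic_vec <- dfcsubtype:::sym_to_edge_vec(analytic_r)
  for (w in c(1, 50, 181)) {
    expect_equal(r_hat[w, ], analytic_vec, tolerance = 1e-8)
  }
})

test_that("noiseless cohorts carry the planted age trends into feature space", {
  # Generator self-consistency: with no subject-level noise, features
  # computed from the planted components themselves must reproduce the
  # planted quadratic age trends almost exactly. (Estimated components add
  # estimation wobble on top; that attenuation is a documented property of
  # the estimation path, not of the generator.)
  gt <- generate_ground_truth(K_true = 4, m = 12, sparsity = 0.15, seed = 8,
                              param_sd = c(ge = 0, fc = 0))
  # plant substantial, known quadratic trends on all features
  gt$age_coefficients$b1 <- rep(c(0.004, 0.02), each = 4) *
    rep(c(1, -1), 4)
  gt$age_coefficients$b2 <- rep(c(2e-4, 5e-4), each = 4)
  coh <- generate_cohort(gt, 0, 40, 2, T_volumes = 210, tr = 2, noise_sd = 0,
                         seed = 8)
  man <- coh$manifest
  ctrl_ids <- man$subject_id[man$group == "control_base"]
  ages <- man$age[match(ctrl_ids, man$subject_id)]
  sp <- coh$truth$subject_params
  L <- 30
  feats <- dplyr::bind_rows(lapply(ctrl_ids, function(sid) {
    del <- sp$delta[sp$subject_id == sid]
    A <- t(vapply(1:4, function(k) {
      gt$patterns[k, ] + del[k] * gt$densifiers[k, ]
    }, numeric(ncol(gt$patterns))))
    Wt <- coh$truth$weight_trajectories[[sid]]
    Wwin <- vapply(seq_len(ncol(Wt) - L + 1), function(t) {
      rowMeans(Wt[, t:(t + L - 1), drop = FALSE])
    }, numeric(4))
    sc <- structure(
      list(subject_id = sid, patterns = A, weights = Wwin,
           roi_labels = sprintf("ROI_%03d", 1:12)),
      class = "subject_components"
    )
    extract_feature_vector(sc)
  }))
  r2 <- vapply(setdiff(names(feats), "subject_id"), function(f) {
    # fc features fit exactly (fluctuation-calibrated weights), which makes
    # summary.lm warn about a perfect fit
    suppressWarnings(summary(lm(feats[[f]] ~ ages + I(ages^2)))$r.squared)
  }, numeric(1))
  expect_true(all(r2 > 0.95))
})

test_that("cohorts round-trip through plain-text files", {
  gt <- generate_ground_truth(K_true = 2, m = 6, sparsity = 0.2, seed = 3)
  coh <- generate_cohort(gt, 2, 1, 1, T_volumes = 40, tr = 2, seed = 3)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$manifest$subject_id, coh$manifest$subject_id)
  expect_equal(back$manifest$age, coh$manifest$age, tolerance = 1e-12)
  for (sid in coh$manifest$subject_id) {
    expect_equal(back$series[[sid]]$data, coh$series[[sid]]$data, tolerance = 1e-12)
  }
})
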