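# Polynomial quantile curves, fold aggregation, and deviation scoring.

test_that("degenerate constant data yields constant curves with zero-width CIs", {
  ages <- seq(20, 48, length.out = 60)
  qc <- fit_quantile_curves(ages, rep(7, 60), n_boot = 50, seed = 1)
  Q <- predict(qc, c(22, 34, 46))
  expect_equal(unname(Q), matrix(7, 3, 3), tolerance = 1e-8)
  td <- tidy(qc)
  expect_equal(td$conf.low, td$conf.high, tolerance = 1e-8)
})

test_that("fitted quantiles satisfy the check-loss balance property", {
  withr::local_seed(12)
  n <- 500
  ages <- runif(n, 18, 50)
  y <- 1 + 0.1 * ages + 0.002 * ages^2 + rnorm(n)
  qc <- fit_quantile_curves(ages, y, n_boot = 0)
  Q <- predict(qc, ages)
  for (ti in seq_along(qc$taus)) {
    frac_below <- mean(y < Q[, ti])
    expect_lt(abs(frac_below - qc$taus[ti]), 2 / sqrt(n))
  }
})

test_that("argument validation rejects malformed quantile problems", {
  ages <- runif(50, 18, 50)
  expect_error(fit_quantile_curves(ages, rnorm(50), taus = c(0.5, 0.9, 1.2)),
               "inside")
  expect_error(fit_quantile_curves(rep(30, 50), rnorm(50)), "design-rank")
  expect_warning(fit_quantile_curves(runif(20, 18, 50), rnorm(20), n_boot = 0),
                 "unstable")
})

test_that("deviation z reproduces its defining formula and properties", {
  # crafted degree-0 curves with q5 = 2, q50 = 3, q95 = 6
  curves <- structure(
    list(feature_name = "f", degree = 0, taus = c(0.05, 0.5, 0.95),
         beta_std = matrix(c(2, 3, 6), 3, 1), center = 30, scale = 5,
         coefficients = matrix(c(2, 3, 6), 3, 1), boot_ci = NULL,
         n_fit = 100, age_range = c(18, 50), ages = NULL, values = NULL),
    class = "quantile_curves"
  )
  expect_equal(deviation_z(5, 30, curves), (5 - 3) / (6 - 2), tolerance = 1e-12)
  expect_equal(deviation_z(3, 41, curves), 0, tolerance = 1e-12)
  # strictly increasing in the observed value
  zs <- deviation_z(seq(0, 8, 0.5), 30, curves)
  expect_true(all(diff(zs) > 0))
  # degenerate scale errors out
  flat <- curves
  flat$beta_std <- matrix(c(3, 3, 3), 3, 1)
  expect_error(deviation_z(5, 30, flat), "degenerate scale")
})

test_that("z-scores are invariant to rescaling feature and controls together", {
  withr::local_seed(31)
  ages <- runif(300, 18, 50)
  y <- 2 + 0.05 * ages + rnorm(300, 0, 0.5)
  qc1 <- fit_quantile_curves(ages, y, n_boot = 0)
  qc2 <- fit_quantile_curves(ages, 10 * y, n_boot = 0)
  expect_equal(deviation_z(3.1, 35, qc1), deviation_z(31, 35, qc2),
               tolerance = 1e-6)
})

test_that("10-fold aggregation partitions controls and fits out-of-fold", {
  withr::local_seed(44)
  controls <- tibble::tibble(
    subject_id = sprintf("c%03d", 1:91),
    age = runif(91, 18, 50),
    f1 = rnorm(91, 5), f2 = rnorm(91, 1)
  )
  model <- fit_aggregate_normative(controls, feature_cols = c("f1", "f2"),
                                   seed = 2)
  fa <- model$fold_assignment
  expect_equal(sort(unique(fa$fold)), 1:10)
  expect_true(all(table(fa$fold) %in% c(9, 10)))
  # each curve was fitted on the controls outside its fold (81 or 82)
  for (f in 1:10) {
    expect_equal(model$folds[[f]]$f1$n_fit, 91 - sum(fa$fold == f))
  }
  expect_error(fit_aggregate_normative(controls[1:5, ],
                                       feature_cols = "f1", n_folds = 10),
               "folds")
})

test_that("identical fold models make the aggregate equal a single model", {
  withr::local_seed(55)
  controls <- tibble::tibble(
    subject_id = sprintf("c%03d", 1:80),
    age = runif(80, 18, 50),
    f1 = rnorm(80)
  )
  model <- fit_aggregate_normative(controls, feature_cols = "f1", seed = 3)
  # overwrite every fold with fold 1: aggregate mean must equal fold 1 alone
  for (f in 2:10) model$folds[[f]] <- model$folds[[1]]
  patients <- tibble::tibble(subject_id = "p1", age = 33, f1 = 1.2)
  z <- score_cohort(patients, model)
  z_single <- deviation_z(1.2, 33, model$folds[[1]]$f1)
  expect_equal(z$f1, z_single, tolerance = 1e-12)
  # out-of-range ages warn but still score
  expect_warning(score_cohort(tibble::tibble(subject_id = "p2", age = 80,
                                             f1 = 1), model),
                 "extrapolat")
})

test_that("held-out control scores are centred near zero", {
  withr::local_seed(66)
  n <- 200
  controls <- tibble::tibble(
    subject_id = sprintf("c%03d", 1:n),
    age = runif(n, 18, 50)
  )
  controls$f1 <- 1 + 0.05 * controls$age + rnorm(n, 0, 0.7)
  model <- fit_aggregate_normative(controls, feature_cols = "f1", seed = 4)
  z <- score_controls_heldout(model, controls)
  expect_lt(abs(mean(z$f1)), 0.1)
  expect_lt(abs(mean(z$f1 > 0) - 0.5), 0.1)
})
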