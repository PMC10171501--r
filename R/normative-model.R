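# Age-referenced normative modelling: per-feature polynomial quantile
# curves (5th / 50th / 95th percentile by default) fitted on healthy
# controls by pinball-loss minimization, aggregated over a 10-fold
# cross-validation ensemble, and used to score individual deviations
#   z = (c_real - q50(age)) / (q95(age) - q5(age)).

# Pinball (check) loss.
pinball_loss <- function(r, tau) sum(r * (tau - (r < 0)))

# Quantile regression of y on design X by iteratively reweighted least
# squares on the check loss. Returns the coefficient vector with the lowest
# pinball loss encountered.
rq_irls <- function(X, y, tau, max_iter = 100, tol = 1e-10) {
  eps <- 1e-6 * max(sd(y), 1e-12)
  beta <- qr.solve(X, y)
  best <- beta
  best_loss <- pinball_loss(y - X %*% beta, tau)
  for (it in seq_len(max_iter)) {
    r <- drop(y - X %*% beta)
    w <- ifelse(r > 0, tau, 1 - tau) / pmax(abs(r), eps)
    fit <- lm.wfit(X, y, w)
    beta_new <- fit$coefficients
    loss <- pinball_loss(y - X %*% beta_new, tau)
    if (loss < best_loss) { best <- beta_new; best_loss <- loss }
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) break
    beta <- beta_new
  }
  best
}

# Convert coefficients in the standardized basis u = (age - center)/scale
# to raw-age polynomial coefficients.
std_to_raw_coef <- function(beta, center, scale) {
  deg <- length(beta) - 1L
  raw <- numeric(deg + 1L)
  for (d in 0:deg) {
    # beta_d * ((a - c)/s)^d expanded in powers of a
    for (p in 0:d) {
      raw[p + 1L] <- raw[p + 1L] +
        beta[d + 1L] * choose(d, p) * (-center)^(d - p) / scale^d
    }
  }
  raw
}

#' Fit polynomial quantile curves for one feature
#'
#' Minimizes the pinball loss of a degree-`degree` polynomial in age for
#' each requested quantile, with optional bootstrap percentile confidence
#' intervals. Predicted quantiles are rearranged to be non-crossing at each
#' evaluated age.
#'
#' @param ages Numeric ages in years (non-constant).
#' @param values Feature values, same length.
#' @param taus Strictly increasing quantile levels in (0, 1); must include
#'   0.5 for downstream deviation scoring. Default `c(0.05, 0.50, 0.95)`.
#' @param degree Polynomial degree (default 2).
#' @param n_boot Bootstrap resamples for coefficient CIs (default 1000;
#'   0 skips the bootstrap).
#' @param seed Integer seed for the bootstrap.
#' @param feature_name Label carried into the result.
#' @param conf Confidence level for the bootstrap CIs.
#' @return A `quantile_curves` object.
#' @export
fit_quantile_curves <- function(ages, values, taus = c(0.05, 0.50, 0.95),
                                degree = 2, n_boot = 1000, seed = 1L,
                                feature_name = "feature", conf = 0.95) {
  if (any(taus <= 0 | taus >= 1)) abort("`taus` must lie strictly inside (0, 1).")
  if (is.unsorted(taus, strictly = TRUE)) abort("`taus` must be strictly increasing.")
  n <- length(ages)
  if (length(values) != n) abort("`ages` and `values` lengths differ.")
  if (sd(ages) == 0) abort("design-rank error: ages are constant.")
  if (n < 3 * (degree + 1)) abort(sprintf("need at least %d observations.", 3 * (degree + 1)))
  if (n < 10 * (degree + 1)) {
    warn(sprintf("only %d observations for a degree-%d quantile fit; curves may be unstable.",
                 n, degree))
  }

  center <- mean(ages)
  scale <- sd(ages)
  u <- (ages - center) / scale
  X <- outer(u, 0:degree, `^`)

  beta <- t(vapply(taus, function(tau) rq_irls(X, values, tau), numeric(degree + 1)))
  rownames(beta) <- paste0("tau_", taus)

  boot_ci <- NULL
  if (n_boot > 0) {
    withr::local_seed(seed)
    boots <- array(NA_real_, c(n_boot, length(taus), degree + 1))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (sd(ages[idx]) == 0) next
      ub <- (ages[idx] - center) / scale
      Xb <- outer(ub, 0:degree, `^`)
      for (ti in seq_along(taus)) {
        boots[b, ti, ] <- std_to_raw_coef(rq_irls(Xb, values[idx], taus[ti]), center, scale)
      }
    }
    a <- (1 - conf) / 2
    boot_ci <- bind_rows(lapply(seq_along(taus), function(ti) {
      tibble(
        tau = taus[ti],
        term = paste0("age^", 0:degree),
        conf.low = apply(boots[, ti, , drop = FALSE], 3, quantile, probs = a, na.rm = TRUE),
        conf.high = apply(boots[, ti, , drop = FALSE], 3, quantile, probs = 1 - a, na.rm = TRUE)
      )
    }))
  }

  structure(
    list(feature_name = feature_name, degree = degree, taus = taus,
         beta_std = beta, center = center, scale = scale,
         coefficients = t(apply(beta, 1, std_to_raw_coef, center = center, scale = scale)),
         boot_ci = boot_ci, n_fit = n, age_range = range(ages),
         ages = ages, values = values),
    class = "quantile_curves"
  )
}

#' Predict quantile curves at new ages
#'
#' @param object A `quantile_curves` object.
#' @param ages Ages at which to evaluate.
#' @param ... Unused.
#' @return A matrix `length(ages) x length(taus)`; each row is sorted
#'   (monotone rearrangement) so quantiles never cross.
#' @export
predict.quantile_curves <- function(object, ages, ...) {
  u <- (ages - object$center) / object$scale
  X <- outer(u, 0:object$degree, `^`)
  Q <- X %*% t(object$beta_std)
  Q <- t(apply(Q, 1, sort))
  colnames(Q) <- sprintf("q%g", 100 * object$taus)
  Q
}

#' @export
print.quantile_curves <- function(x, ...) {
  cat(sprintf("<quantile_curves> '%s': degree %d, taus %s, n = %d\n",
              x$feature_name, x$degree, paste(x$taus, collapse = "/"), x$n_fit))
  invisible(x)
}

#' @export
#' @exportS3Method generics::tidy
tidy.quantile_curves <- function(x, ...) {
  out <- bind_rows(lapply(seq_along(x$taus), function(ti) {
    tibble(tau = x$taus[ti], term = paste0("age^", 0:x$degree),
           estimate = x$coefficients[ti, ])
  }))
  if (!is.null(x$boot_ci)) out <- left_join(out, x$boot_ci, by = c("tau", "term"))
  out
}

#' @export
#' @exportS3Method generics::glance
glance.quantile_curves <- function(x, ...) {
  tibble(feature = x$feature_name, degree = x$degree, n = x$n_fit,
         age_min = x$age_range[1], age_max = x$age_range[2])
}

#' Deviation z-score against fitted quantile curves
#'
#' `z = (c_real - q50(age)) / (q95(age) - q5(age))`: the observed value's
#' offset from the predicted median, scaled by the predicted 5th-95th
#' percentile span at the same age.
#'
#' @param c_real Observed feature value(s).
#' @param age Age(s) in years, recycled against `c_real`.
#' @param curves A [fit_quantile_curves()] object whose `taus` include 0.5.
#' @return Numeric z-score(s).
#' @export
#' @examples
#' # (5 - 3) / (6 - 2) = 0.5 for constant curves q5 = 2, q50 = 3, q95 = 6
deviation_z <- function(c_real, age, curves) {
  stopifnot(inherits(curves, "quantile_curves"))
  mid <- which(abs(curves$taus - 0.5) < 1e-12)
  if (length(mid) != 1) abort("curves must include the 0.5 quantile.")
  n <- max(length(c_real), length(age))
  c_real <- rep_len(c_real, n)
  age <- rep_len(age, n)
  Q <- predict(curves, age)
  span <- Q[, ncol(Q)] - Q[, 1]
  if (any(span <= 0)) {
    abort("degenerate scale: upper and lower quantile curves coincide at some age.")
  }
  unname((c_real - Q[, mid]) / span)
}

#' Fit a 10-fold aggregate normative model
#'
#' Controls are assigned to folds at random, stratified by age decile; each
#' fold's curves are fitted on the controls outside that fold, for every
#' feature.
#'
#' @param controls Tibble with `subject_id`, an age column and the feature
#'   columns.
#' @param feature_cols Character vector of feature columns; default all
#'   numeric columns except the age column.
#' @param age_col Name of the age column (default `"age"`).
#' @param n_folds Number of folds (default 10).
#' @param taus,degree,n_boot Passed to [fit_quantile_curves()]; `n_boot`
#'   defaults to 0 here because the CIs are not consumed downstream.
#' @param seed Integer seed for fold assignment.
#' @return A `normative_model` object.
#' @export
fit_aggregate_normative <- function(controls, feature_cols = NULL,
                                    age_col = "age", n_folds = 10,
                                    taus = c(0.05, 0.50, 0.95), degree = 2,
                                    n_boot = 0, seed = 1L) {
  controls <- as_tibble(controls)
  n <- nrow(controls)
  if (n_folds > n) abort(sprintf("%d folds requested for %d controls.", n_folds, n))
  if (!age_col %in% names(controls)) abort(sprintf("no '%s' column.", age_col))
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(controls)[vapply(controls, is.numeric, logical(1))],
                            c(age_col, "mean_fd", "max_fd", "education", "illness_duration"))
  }
  ages <- controls[[age_col]]

  withr::local_seed(seed)
  # Age-stratified, size-balanced folds: walk subjects in age order in
  # blocks of n_folds and deal a random permutation of fold labels to each
  # block, so folds differ in size by at most one and span all age deciles.
  strata <- cut(rank(ages, ties.method = "first"),
                breaks = min(10L, n), labels = FALSE)
  fold <- integer(n)
  ord <- order(ages)
  pos <- 1L
  while (pos <= n) {
    block <- ord[pos:min(pos + n_folds - 1L, n)]
    fold[block] <- sample(n_folds)[seq_along(block)]
    pos <- pos + n_folds
  }

  ids <- if ("subject_id" %in% names(controls)) controls$subject_id else as.character(seq_len(n))
  folds <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    train <- fold != f
    if (any(table(strata[train]) == 0)) {
      warn(sprintf("fold %d empties an age stratum; its curves extrapolate there.", f))
    }
    folds[[f]] <- lapply(setNames(feature_cols, feature_cols), function(fc) {
      fit_quantile_curves(ages[train], controls[[fc]][train], taus = taus,
                          degree = degree, n_boot = n_boot,
                          seed = derive_seed(seed, paste0(fc, f)),
                          feature_name = fc)
    })
  }

  structure(
    list(folds = folds, fold_assignment = tibble(subject_id = ids, fold = fold),
         feature_names = feature_cols, taus = taus, degree = degree,
         age_col = age_col, n_folds = n_folds,
         age_range = range(ages)),
    class = "normative_model"
  )
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("<normative_model> %d features x %d folds, degree %d, ages %.1f-%.1f\n",
              length(x$feature_names), x$n_folds, x$degree,
              x$age_range[1], x$age_range[2]))
  invisible(x)
}

#' @export
#' @exportS3Method generics::tidy
tidy.normative_model <- function(x, ...) {
  bind_rows(imap(x$folds, function(fl, f) {
    bind_rows(lapply(fl, tidy)) |>
      mutate(fold = as.integer(f),
             feature = rep(vapply(fl, function(q) q$feature_name, character(1)),
                           each = length(x$taus) * (x$degree + 1)))
  }))
}

#' Score subjects against an aggregate normative model
#'
#' Each subject is scored by all fold models; the reported z is the
#' per-feature mean of the fold z-scores. Ages outside the fitted range are
#' scored with an extrapolation warning.
#'
#' @param subjects Tibble with `subject_id`, the age column and the model's
#'   feature columns.
#' @param model A [fit_aggregate_normative()] object.
#' @return A wide tibble (`subject_id` + one z column per feature) with a
#'   `per_fold` attribute holding the long per-fold scores.
#' @export
score_cohort <- function(subjects, model) {
  stopifnot(inherits(model, "normative_model"))
  subjects <- as_tibble(subjects)
  ages <- subjects[[model$age_col]]
  if (any(ages < model$age_range[1] | ages > model$age_range[2])) {
    warn("some ages fall outside the fitted range; scores are extrapolated.")
  }
  n <- nrow(subjects)
  nf <- length(model$feature_names)
  per_fold <- array(NA_real_, c(n, nf, model$n_folds),
                    dimnames = list(NULL, model$feature_names, NULL))
  for (f in seq_len(model$n_folds)) {
    for (fc in model$feature_names) {
      per_fold[, fc, f] <- deviation_z(subjects[[fc]], ages, model$folds[[f]][[fc]])
    }
  }
  z <- apply(per_fold, c(1, 2), mean)
  out <- bind_cols(tibble(subject_id = subjects$subject_id), as_tibble(z))
  long <- bind_rows(lapply(seq_len(model$n_folds), function(f) {
    tibble(subject_id = rep(subjects$subject_id, times = nf),
           feature = rep(model$feature_names, each = n),
           fold = f, z = as.vector(per_fold[, , f]))
  }))
  attr(out, "per_fold") <- long
  out
}

#' Held-out z-scores for the controls a model was fitted on
#'
#' Each control is scored only by the model of its own fold (the fold whose
#' training set excluded it), giving unbiased calibration scores.
#'
#' @param model A [fit_aggregate_normative()] object.
#' @param controls The same control tibble the model was fitted on.
#' @return A wide tibble of held-out z-scores.
#' @export
score_controls_heldout <- function(model, controls) {
  stopifnot(inherits(model, "normative_model"))
  controls <- as_tibble(controls)
  fa <- model$fold_assignment
  idx <- match(controls$subject_id, fa$subject_id)
  if (any(is.na(idx))) abort("controls do not match the model's fold assignment.")
  ages <- controls[[model$age_col]]
  out <- matrix(NA_real_, nrow(controls), length(model$feature_names),
                dimnames = list(NULL, model$feature_names))
  for (i in seq_len(nrow(controls))) {
    f <- fa$fold[idx[i]]
    for (fc in model$feature_names) {
      out[i, fc] <- deviation_z(controls[[fc]][i], ages[i], model$folds[[f]][[fc]])
    }
  }
  bind_cols(tibble(subject_id = controls$subject_id), as_tibble(out))
}
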