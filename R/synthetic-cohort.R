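# Synthetic cohort generator with ground truth at every pipeline stage.
#
# The generative model, per subject i with age a:
#   - K_true sparse symmetric edge patterns C_k (shared) and sparse
#     "densifier" patterns D_k on disjoint supports;
#   - per-component structure parameter delta_ik = ge-trend(a) + noise
#     (+ subtype shift for patients), giving the subject pattern
#     A_ik = C_k + delta_ik * D_k  -> drives the global-efficiency feature;
#   - per-component fluctuation scale s_ik = fc-trend(a) + noise (+ shift),
#     scaling a smoothed Gaussian random-walk weight trajectory
#     w_ik(t) = base + amplitude * s_ik * eta_ik(t) -> drives the
#     fluctuation-coefficient feature;
#   - time-varying covariance Sigma_i(t) = I + sum_k w_ik(t) A_ik, repaired
#     to positive definite by eigenvalue clipping at 1e-6;
#   - BOLD-like series x_t = L_i(t) z_t + noise_sd * eps_t where
#     L L' = Sigma and z_t comes from a periodic exactly-whitened carrier
#     (so in the noiseless limit, window correlations equal the analytic
#     correlation of Sigma when the window length equals the carrier
#     period and m < period).
#
# Subtype shifts are stated in normative z units and converted to parameter
# units as shift_z * 3.29 * sigma_param (3.29 = q95 - q5 span of a standard
# Gaussian), sigma_param being the generator's own between-subject SD.

Z_TO_SPAN <- qnorm(0.95) - qnorm(0.05)  # 3.2897

#' Default planted-subtype specification
#'
#' Two subtypes mirroring the published direction: subtype I (16% of
#' patients) with large positive deviations and subtype II (84%) with weak
#' deviations, on 12 of the 2K features drawn from 10 components
#' (fluctuation coefficients of components 1-9 and global efficiency of
#' components 2, 6, 10, clipped to the available K). Fluctuation features
#' carry the planted shifts essentially undistorted through the pipeline;
#' structural (efficiency) shifts are attenuated by reference-guided
#' pattern estimation, so they act as supporting signal.
#'
#' @param K Number of components.
#' @param shift_I,shift_II Planted deviation shifts in normative z units.
#' @return A list with `proportions` (named numeric, sums to 1) and
#'   `shift_z` (2 x 2K matrix, rows "I" and "II").
#' @export
default_subtype_spec <- function(K, shift_I = 2.0, shift_II = 0.3) {
  ge_idx <- intersect(c(2L, 6L, 10L), seq_len(K))
  fc_idx <- K + seq_len(min(9L, K))
  shift_z <- matrix(0, 2, 2 * K, dimnames = list(c("I", "II"), NULL))
  shift_z["I", c(ge_idx, fc_idx)] <- shift_I
  shift_z["II", c(ge_idx, fc_idx)] <- shift_II
  list(proportions = c(I = 0.16, II = 0.84), shift_z = shift_z)
}

#' Generate ground truth for a synthetic cohort
#'
#' Draws the latent component bank and the population-level generative
#' parameters; [generate_cohort()] consumes the result and attaches the
#' subject-level realizations.
#'
#' @param K_true Number of latent components (>= 1).
#' @param m ROI count (>= 3).
#' @param sparsity Fraction of the E = m(m-1)/2 edges carried by each
#'   component, in (0, 1).
#' @param subtype_spec See [default_subtype_spec()]; `NULL` uses the default.
#' @param seed Integer seed; identical arguments and seed reproduce the
#'   object exactly.
#' @param param_sd Named between-subject SDs of the structure (`ge`) and
#'   fluctuation (`fc`) parameters. Setting both to 0 yields a cohort whose
#'   features are deterministic functions of age.
#' @param max_cosine Upper bound enforced on pairwise |cosine| between
#'   component patterns (default 0.3) so recovery is well-posed.
#' @return A `ground_truth` object: `patterns` and `densifiers` (K x E edge
#'   matrices), `age_coefficients` (per-feature quadratic trend in the
#'   centred age u = age - 34), `subtype_spec`, `deviation_shifts` (in
#'   parameter units), `param_sd`, and bookkeeping.
#' @export
generate_ground_truth <- function(K_true, m, sparsity = 0.1,
                                  subtype_spec = NULL, seed = 1L,
                                  param_sd = c(ge = 0.08, fc = 0.10),
                                  max_cosine = 0.3) {
  stopifnot(K_true >= 1, m >= 3)
  if (sparsity <= 0 || sparsity >= 1) abort("`sparsity` must be in (0, 1).")
  E <- m * (m - 1L) / 2L
  if (K_true > E) {
    abort(sprintf("infeasible rank: K_true = %d exceeds the edge-space dimension E = %d.",
                  K_true, E))
  }
  if (is.null(subtype_spec)) subtype_spec <- default_subtype_spec(K_true)
  props <- subtype_spec$proportions
  if (abs(sum(props) - 1) > 1e-8) abort("subtype proportions must sum to 1.")

  withr::local_seed(seed)
  s_edges <- max(1L, round(sparsity * E))

  # Loadings scale as 1/sqrt(K_true): the spectral radius of a sum of K
  # independent random sparse symmetric patterns grows like sqrt(K), so this
  # keeps Sigma(t) = I + sum_k w_k C_k positive definite at any model order
  # and makes the eigenvalue clip a rare repair rather than a distortion.
  amp <- c(0.18, 0.33) / sqrt(K_true)
  draw_pattern <- function(lo, hi) {
    v <- numeric(E)
    sup <- sample.int(E, s_edges)
    v[sup] <- runif(s_edges, lo, hi) * sample(c(-1, 1), s_edges, replace = TRUE)
    v
  }

  patterns <- matrix(0, K_true, E)
  for (k in seq_len(K_true)) {
    ok <- FALSE
    for (try in seq_len(200)) {
      cand <- draw_pattern(amp[1], amp[2])
      if (k == 1) { ok <- TRUE; patterns[1, ] <- cand; break }
      cosines <- abs(patterns[seq_len(k - 1), , drop = FALSE] %*% cand) /
        (sqrt(rowSums(patterns[seq_len(k - 1), , drop = FALSE]^2)) * sqrt(sum(cand^2)))
      if (all(cosines < max_cosine)) { ok <- TRUE; patterns[k, ] <- cand; break }
    }
    if (!ok) abort("could not draw a near-orthogonal component bank; lower `sparsity` or `K_true`.")
  }

  densifiers <- matrix(0, K_true, E)
  for (k in seq_len(K_true)) {
    free <- which(patterns[k, ] == 0)
    n_d <- min(2L * s_edges, length(free))
    sup <- sample(free, n_d)
    # Densifier edges share the pattern amplitude range and use twice the
    # support: global efficiency aggregates over edges, so at typical delta
    # the densifier must clear the pattern-estimation noise floor on enough
    # edges for the feature to respond to the structure parameter.
    densifiers[k, sup] <- runif(n_d, amp[1], amp[2]) *
      sample(c(-1, 1), n_d, replace = TRUE)
  }

  K2 <- 2L * K_true
  feature_names <- c(sprintf("ge_IC%02d", seq_len(K_true)),
                     sprintf("fc_IC%02d", seq_len(K_true)))
  age_coefficients <- tibble(
    feature = feature_names,
    b0 = rep(c(0.30, 1.00), each = K_true),
    b1 = c(runif(K_true, -0.004, 0.004), runif(K_true, -0.012, 0.012)),
    b2 = c(runif(K_true, -3e-4, 3e-4), runif(K_true, -8e-4, 8e-4)),
    age_center = 34
  )

  sd_per_feature <- rep(c(param_sd[["ge"]], param_sd[["fc"]]), each = K_true)
  deviation_shifts <- sweep(subtype_spec$shift_z, 2, Z_TO_SPAN * sd_per_feature, "*")
  colnames(deviation_shifts) <- feature_names

  structure(
    list(m = m, K_true = K_true, E = E, sparsity = sparsity,
         patterns = patterns, densifiers = densifiers,
         edge_index = edge_index_pairs(m),
         age_coefficients = age_coefficients,
         subtype_spec = subtype_spec,
         deviation_shifts = deviation_shifts,
         param_sd = param_sd, seed = as.integer(seed),
         feature_names = feature_names),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d components over %d ROIs (E = %d), sparsity %.2f, seed %d\n",
              x$K_true, x$m, x$E, x$sparsity, x$seed))
  invisible(x)
}

# Whitened periodic carrier: a P x m block with zero column means and
# sample covariance as close to identity as the rank allows (exactly
# identity when m <= P - 1), tiled over T rows. Because every length-P
# window of the tiling contains one full period, the carrier contributes a
# *constant* covariance to every window: sliding-window estimates carry no
# carrier sampling noise, and in the noiseless limit (m < P, window length
# = P) window correlations equal the analytic correlation of Sigma exactly.
# For m >= P the block covariance is a rank-(P-1) projection — constant
# across windows, so still noiseless, at the price of a low-rank carrier.
make_carrier <- function(T_len, m, period) {
  Z0 <- matrix(rnorm(period * m), period, m)
  Z0 <- sweep(Z0, 2, colMeans(Z0))
  sv <- svd(Z0)
  r <- sum(sv$d > 1e-10 * sv$d[1])
  Z0 <- sv$u[, seq_len(r), drop = FALSE] %*% t(sv$v[, seq_len(r), drop = FALSE]) *
    sqrt(period - 1)
  reps <- ceiling(T_len / period)
  Z0[rep(seq_len(period), reps)[seq_len(T_len)], , drop = FALSE]
}

# Smoothed standardized random-walk trajectory with calibrated windowed
# fluctuation: after scaling, the mean absolute first difference of its
# running window means equals `fluct_ref` exactly.
make_weight_carrier <- function(T_len, smooth_width, fluct_ref = 0.02) {
  eta <- cumsum(rnorm(T_len + 2L * smooth_width))
  eta <- moving_average(eta, smooth_width)[(smooth_width + 1L):(smooth_width + T_len)]
  eta <- (eta - mean(eta)) / sd(eta)
  wm <- as.numeric(stats::filter(eta, rep(1 / smooth_width, smooth_width), sides = 1))
  wm <- wm[!is.na(wm)]
  q <- mean(abs(diff(wm)))
  if (q > 0) eta <- eta * (fluct_ref / q)
  eta
}

#' Generate a synthetic cohort
#'
#' Samples a manifest (demographics, motion summaries, planted subtype
#' labels) and per-subject ROI time series from the ground truth's
#' time-varying covariance model. Patients carry the subtype deviation
#' shifts; every subject carries the quadratic age trends.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param n_patients,n_controls_base,n_controls_ica Group sizes. Defaults
#'   mirror the published cohort (91 patients, 91 matched-control template,
#'   125 ICA-guidance controls).
#' @param T_volumes Number of volumes per subject (default 210).
#' @param tr Repetition time in seconds (default 2).
#' @param noise_sd SD of additive white measurement noise (default 0.02;
#'   signal variance is ~1 per ROI).
#' @param seed Integer seed.
#' @param carrier_period Period (volumes) of the exactly-whitened signal
#'   carrier; equals the default 60 s / TR 2 s window of 30 volumes so the
#'   noiseless limit is exact under the default window.
#' @param weight_base,weight_amplitude Mean level and scale of the
#'   component weight trajectories.
#' @return A list with `manifest` (tibble, one row per subject), `series`
#'   (named list of [roi_timeseries()]), and `truth` (the input ground truth
#'   augmented with `subtype_labels`, `subject_params` and
#'   `weight_trajectories`).
#' @export
generate_cohort <- function(truth, n_patients = 91, n_controls_base = 91,
                            n_controls_ica = 125, T_volumes = 210, tr = 2,
                            noise_sd = 0.02, seed = 1L, carrier_period = 30L,
                            weight_base = 0.6, weight_amplitude = 0.3) {
  stopifnot(inherits(truth, "ground_truth"))
  if (T_volumes <= 0 || tr <= 0) abort("`T_volumes` and `tr` must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  m <- truth$m; K <- truth$K_true
  n_total <- n_patients + n_controls_base + n_controls_ica

  withr::local_seed(seed)

  subject_id <- sprintf("sub-%04d", seq_len(n_total))
  group <- rep(c("patient", "control_base", "control_ica"),
               c(n_patients, n_controls_base, n_controls_ica))

  # Planted subtype labels with deterministic rounding of proportions.
  props <- truth$subtype_spec$proportions
  n_I <- round(props[["I"]] * n_patients)
  subtype <- rep(NA_character_, n_total)
  lab <- c(rep("I", n_I), rep("II", n_patients - n_I))
  subtype[seq_len(n_patients)] <- sample(lab)

  age <- runif(n_total, 18, 50)
  sex <- ifelse(runif(n_total) < 0.65, "F", "M")
  education <- pmin(pmax(round(rnorm(n_total, 12, 3.3)), 6), 22)
  mean_fd <- pmax(abs(rnorm(n_total, 0.07, 0.04)), 0.005)
  max_fd <- mean_fd * runif(n_total, 3, 8)

  # Illness duration (months): subtype-specific lognormals calibrated to
  # mean/sd 11.75 +/- 12.09 (I) and 22.1 +/- 23.92 (II).
  lnorm_pars <- function(mu, s) {
    sig2 <- log(1 + (s / mu)^2)
    c(meanlog = log(mu) - sig2 / 2, sdlog = sqrt(sig2))
  }
  p_I <- lnorm_pars(11.75, 12.09); p_II <- lnorm_pars(22.1, 23.92)
  illness_duration <- rep(NA_real_, n_total)
  is_I <- !is.na(subtype) & subtype == "I"
  is_II <- !is.na(subtype) & subtype == "II"
  illness_duration[is_I] <- rlnorm(sum(is_I), p_I["meanlog"], p_I["sdlog"])
  illness_duration[is_II] <- rlnorm(sum(is_II), p_II["meanlog"], p_II["sdlog"])

  manifest <- tibble(
    subject_id = subject_id, group = group, subtype = subtype,
    age = age, sex = sex, education = as.numeric(education),
    illness_duration = illness_duration,
    mean_fd = mean_fd, max_fd = max_fd
  )

  # Per-subject, per-component generative parameters.
  ac <- truth$age_coefficients
  u <- age - ac$age_center[1]
  trend <- function(f_idx) ac$b0[f_idx] + ac$b1[f_idx] * u + ac$b2[f_idx] * u^2
  sd_ge <- truth$param_sd[["ge"]]; sd_fc <- truth$param_sd[["fc"]]

  delta <- matrix(0, n_total, K)   # structure parameter (ge features)
  sfl <- matrix(0, n_total, K)     # fluctuation scale (fc features)
  for (k in seq_len(K)) {
    delta[, k] <- trend(k) + rnorm(n_total, 0, sd_ge)
    sfl[, k] <- trend(K + k) + rnorm(n_total, 0, sd_fc)
    shift_ge <- truth$deviation_shifts[, k]
    shift_fc <- truth$deviation_shifts[, K + k]
    delta[is_I, k] <- delta[is_I, k] + shift_ge[["I"]]
    delta[is_II, k] <- delta[is_II, k] + shift_ge[["II"]]
    sfl[is_I, k] <- sfl[is_I, k] + shift_fc[["I"]]
    sfl[is_II, k] <- sfl[is_II, k] + shift_fc[["II"]]
  }
  delta <- pmax(delta, 0)
  sfl <- pmax(sfl, 0.05)

  roi_labels <- sprintf("ROI_%03d", seq_len(m))
  pat_mats <- lapply(seq_len(K), function(k) edge_vec_to_sym(truth$patterns[k, ], m))
  den_mats <- lapply(seq_len(K), function(k) edge_vec_to_sym(truth$densifiers[k, ], m))

  series <- vector("list", n_total)
  names(series) <- subject_id
  weight_trajectories <- vector("list", n_total)
  names(weight_trajectories) <- subject_id

  for (i in seq_len(n_total)) {
    A <- lapply(seq_len(K), function(k) pat_mats[[k]] + delta[i, k] * den_mats[[k]])
    Wmat <- matrix(0, K, T_volumes)
    for (k in seq_len(K)) {
      eta <- make_weight_carrier(T_volumes, carrier_period)
      Wmat[k, ] <- weight_base + weight_amplitude * sfl[i, k] * eta
    }
    Z <- make_carrier(T_volumes, m, carrier_period)
    R <- qr.Q(qr(matrix(rnorm(m * m), m, m)))
    Z <- Z %*% R
    X <- matrix(0, T_volumes, m)
    for (t in seq_len(T_volumes)) {
      Sig <- diag(m)
      for (k in seq_len(K)) Sig <- Sig + Wmat[k, t] * A[[k]]
      Lf <- tryCatch(t(chol(Sig)), error = function(e) nearest_pd(Sig)$sqrt)
      X[t, ] <- Lf %*% Z[t, ]
    }
    if (noise_sd > 0) X <- X + matrix(rnorm(T_volumes * m, 0, noise_sd), T_volumes, m)
    colnames(X) <- roi_labels
    series[[i]] <- roi_timeseries(X, tr = tr, subject_id = subject_id[i],
                                  roi_labels = roi_labels)
    weight_trajectories[[i]] <- Wmat
  }

  truth$subtype_labels <- setNames(subtype[seq_len(n_patients)], subject_id[seq_len(n_patients)])
  truth$subject_params <- tibble(
    subject_id = rep(subject_id, each = K),
    component = rep(seq_len(K), times = n_total),
    delta = as.vector(t(delta)),
    fluct_scale = as.vector(t(sfl))
  )
  truth$weight_trajectories <- weight_trajectories
  truth$cohort_seed <- as.integer(seed)
  truth$noise_sd <- noise_sd
  truth$weight_base <- weight_base
  truth$weight_amplitude <- weight_amplitude

  list(manifest = manifest, series = series, truth = truth)
}

#' Write / read a synthetic cohort as plain text
#'
#' The manifest goes to `manifest.csv`, each subject's series to
#' `series/<subject_id>.tsv`, and the ground truth (component bank, trends,
#' labels, parameters) to `ground_truth.json`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "series"), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$manifest, file.path(dir, "manifest.csv"), progress = FALSE)
  for (ts in cohort$series) {
    write_timeseries(ts, file.path(dir, "series", paste0(ts$subject_id, ".tsv")))
  }
  tr <- cohort$truth
  gt <- list(
    m = tr$m, K_true = tr$K_true, sparsity = tr$sparsity, seed = tr$seed,
    patterns = apply(tr$patterns, 1, identity, simplify = FALSE),
    densifiers = apply(tr$densifiers, 1, identity, simplify = FALSE),
    age_coefficients = tr$age_coefficients,
    subtype_labels = as.list(tr$subtype_labels),
    deviation_shifts = apply(tr$deviation_shifts, 1, identity, simplify = FALSE),
    param_sd = as.list(tr$param_sd),
    tr_seconds = cohort$series[[1]]$tr
  )
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @param tr Repetition time used when re-reading the series; defaults to
#'   the value recorded in `ground_truth.json` when present.
#' @export
read_cohort <- function(dir, tr = NULL) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE, progress = FALSE)
  gt_path <- file.path(dir, "ground_truth.json")
  if (is.null(tr)) {
    if (!file.exists(gt_path)) abort("`tr` must be given when ground_truth.json is absent.")
    tr <- jsonlite::read_json(gt_path)$tr_seconds
  }
  series <- lapply(manifest$subject_id, function(sid) {
    read_timeseries(file.path(dir, "series", paste0(sid, ".tsv")), tr = tr,
                    subject_id = sid)
  })
  names(series) <- manifest$subject_id
  list(manifest = manifest, series = series)
}
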