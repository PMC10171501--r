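# Subject-level quality control and control matching. Both operations only
# partition or subset manifest rows; they never mutate them.

#' Head-motion quality control
#'
#' Retains subjects whose frame-wise displacement (FD) summaries satisfy the
#' inclusion rule. The default rule is the literal disjunction
#' `mean_fd <= mean_fd_max OR max_fd <= max_fd_max`; a conjunctive variant is
#' available because the intended logic of the published rule is ambiguous.
#'
#' @param manifest A manifest tibble with numeric `mean_fd` and `max_fd`
#'   columns (mm).
#' @param mean_fd_max Threshold on mean FD in mm (default 0.5).
#' @param max_fd_max Threshold on maximum FD in mm (default 2).
#' @param rule `"or"` (default) or `"and"`.
#' @return A list with tibbles `kept` and `excluded`, both preserving the
#'   input row order.
#' @export
qc_filter_fd <- function(manifest, mean_fd_max = 0.5, max_fd_max = 2,
                         rule = c("or", "and")) {
  rule <- arg_match(rule)
  manifest <- as_tibble(manifest)
  miss <- setdiff(c("mean_fd", "max_fd"), names(manifest))
  if (length(miss) > 0) {
    abort(paste0("manifest is missing FD column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(manifest$mean_fd)) || any(!is.finite(manifest$max_fd)) ||
      any(manifest$mean_fd < 0) || any(manifest$max_fd < 0)) {
    abort("FD columns must be finite and non-negative.")
  }
  pass_mean <- manifest$mean_fd <= mean_fd_max
  pass_max <- manifest$max_fd <= max_fd_max
  keep <- if (rule == "or") pass_mean | pass_max else pass_mean & pass_max
  list(kept = manifest[keep, , drop = FALSE],
       excluded = manifest[!keep, , drop = FALSE])
}

#' Match controls to patients
#'
#' Greedy 1:1 nearest-neighbour matching without replacement on standardized
#' covariates using Mahalanobis distance, with exact sex matching where
#' possible. Patients are visited in a seeded random order; each is paired
#' with its closest unused control.
#'
#' @param patients,controls Manifest tibbles. `controls` must have at least
#'   as many rows as `patients`.
#' @param covariates Character vector of covariate columns (default
#'   `c("age", "sex", "education")`; `sex` is matched exactly when a
#'   same-sex control remains, and excluded from the distance).
#' @param seed Integer seed for the patient visiting order.
#' @return The matched subset of `controls` (one row per patient) with a
#'   `matched_to` column naming the patient each control was matched to.
#' @export
match_controls <- function(patients, controls,
                           covariates = c("age", "sex", "education"),
                           seed = 1L) {
  patients <- as_tibble(patients)
  controls <- as_tibble(controls)
  if (nrow(controls) < nrow(patients)) {
    abort(sprintf("infeasible matching: %d controls for %d patients.",
                  nrow(controls), nrow(patients)))
  }
  miss <- setdiff(covariates, union(names(patients), names(controls)))
  if (length(miss) > 0) abort(paste0("missing covariate(s): ", paste(miss, collapse = ", ")))

  exact_sex <- "sex" %in% covariates
  num_cov <- setdiff(covariates, "sex")

  pm <- as.matrix(as.data.frame(lapply(patients[num_cov], as.numeric)))
  cm <- as.matrix(as.data.frame(lapply(controls[num_cov], as.numeric)))
  pooled <- rbind(pm, cm)
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2, sd)
  sdv[sdv == 0] <- 1
  pm <- sweep(sweep(pm, 2, mu), 2, sdv, "/")
  cm <- sweep(sweep(cm, 2, mu), 2, sdv, "/")
  S <- stats::cov(rbind(pm, cm))
  # Guard against singular covariance on degenerate inputs.
  Sinv <- tryCatch(solve(S), error = function(e) solve(S + diag(1e-8, ncol(S))))

  withr::local_seed(seed)
  order_p <- sample.int(nrow(patients))
  used <- rep(FALSE, nrow(controls))
  match_idx <- integer(nrow(patients))
  for (p in order_p) {
    cand <- which(!used)
    if (exact_sex) {
      same <- cand[controls$sex[cand] == patients$sex[p]]
      if (length(same) > 0) cand <- same
    }
    diff <- sweep(cm[cand, , drop = FALSE], 2, pm[p, ])
    d2 <- rowSums((diff %*% Sinv) * diff)
    best <- cand[which.min(d2)]
    match_idx[p] <- best
    used[best] <- TRUE
  }
  out <- controls[match_idx, , drop = FALSE]
  out$matched_to <- if ("subject_id" %in% names(patients)) {
    patients$subject_id
  } else {
    as.character(seq_len(nrow(patients)))
  }
  out
}

#' Standardized mean difference of a covariate between two groups
#'
#' Balance diagnostic used to assess matching quality:
#' `(mean_a - mean_b) / sd_pooled`.
#'
#' @param a,b Numeric vectors.
#' @return A single number (0 when both groups are identical in mean).
#' @export
standardized_mean_diff <- function(a, b) {
  sp <- sqrt((var(a) + var(b)) / 2)
  if (!is.finite(sp) || sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}
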