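# End-to-end orchestration: QC -> control matching -> dFC -> group ICA on
# the ICA-guidance controls -> guided subject ICA -> features -> normative
# model on the base controls -> patient deviations -> feature selection +
# clustering -> covariate-adjusted permutation contrasts. All randomness
# flows from a single root seed expanded into named per-stage substreams.

#' Pipeline configuration
#'
#' Collects every tunable parameter with the published defaults: 60 s
#' windows stepped by 1 volume, K = 20 components, degree-2 normative
#' curves at the 5th/50th/95th percentiles with 10-fold aggregation,
#' 100-run selection and clustering at k = 2, frequency threshold 0.8,
#' certainty threshold 0.6, and 5000 permutations at alpha = 0.01.
#'
#' @param window_length_s Sliding-window length in seconds.
#' @param step_volumes Window step in volumes.
#' @param n_components Number of independent components K.
#' @param normative_degree Polynomial degree of the normative curves.
#' @param percentiles Quantile levels in percent (strictly increasing).
#' @param n_folds Normative aggregation folds.
#' @param n_boot Bootstrap resamples for normative CIs (0 = skip; the CIs
#'   are reported, never consumed downstream).
#' @param n_cluster_runs Repeated runs for selection and clustering.
#' @param k Number of clusters.
#' @param selection_frequency_threshold Informative-feature threshold.
#' @param certainty_threshold Subject exclusion threshold on certainty.
#' @param n_permutations Permutations for the group contrasts.
#' @param alpha_edge Per-feature significance threshold.
#' @param mean_fd_max,max_fd_max,fd_rule Head-motion QC parameters; see
#'   [qc_filter_fd()].
#' @param lambda_ref Guidance blend of the subject ICA; see
#'   [fit_subject_components()].
#' @param taper Window taper; see [sliding_window_fc()].
#' @param seed Root seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(window_length_s = 60, step_volumes = 1,
                            n_components = 20, normative_degree = 2,
                            percentiles = c(5, 50, 95), n_folds = 10,
                            n_boot = 0, n_cluster_runs = 100, k = 2,
                            selection_frequency_threshold = 0.8,
                            certainty_threshold = 0.6,
                            n_permutations = 5000, alpha_edge = 0.01,
                            mean_fd_max = 0.5, max_fd_max = 2,
                            fd_rule = "or", lambda_ref = 0.5,
                            taper = "none", seed = 1L) {
  cfg <- list(
    window_length_s = window_length_s, step_volumes = step_volumes,
    n_components = n_components, normative_degree = normative_degree,
    percentiles = percentiles, n_folds = n_folds, n_boot = n_boot,
    n_cluster_runs = n_cluster_runs, k = k,
    selection_frequency_threshold = selection_frequency_threshold,
    certainty_threshold = certainty_threshold,
    n_permutations = n_permutations, alpha_edge = alpha_edge,
    mean_fd_max = mean_fd_max, max_fd_max = max_fd_max, fd_rule = fd_rule,
    lambda_ref = lambda_ref, taper = taper, seed = as.integer(seed)
  )
  counts <- c("n_components", "n_folds", "n_cluster_runs", "k", "n_permutations",
              "step_volumes")
  for (nm in counts) {
    if (cfg[[nm]] < 1) abort(sprintf("`%s` must be a positive count.", nm))
  }
  for (nm in c("selection_frequency_threshold", "certainty_threshold", "alpha_edge")) {
    if (cfg[[nm]] <= 0 || cfg[[nm]] > 1) abort(sprintf("`%s` must be in (0, 1].", nm))
  }
  if (is.unsorted(percentiles, strictly = TRUE)) {
    abort("`percentiles` must be strictly increasing.")
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-30s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Run the full subtype-discovery pipeline
#'
#' Executes the stages in order on a cohort (manifest + named list of ROI
#' time series): head-motion QC, control matching, sliding-window dFC,
#' group ICA on the `control_ica` group, guided subject ICA for patients
#' and matched base controls, feature extraction, normative modelling on
#' the matched controls, deviation scoring, wrapper feature selection,
#' repeated clustering, and permutation contrasts (control vs each subtype
#' and subtype I vs II) adjusted for age, sex and education.
#'
#' @param manifest Tibble with `subject_id`, `group`
#'   (`patient` / `control_base` / `control_ica`), `age`, `sex`,
#'   `education`, `mean_fd`, `max_fd`.
#' @param series Named list of [roi_timeseries()] keyed by `subject_id`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, tabular intermediates are
#'   persisted as CSV/JSON.
#' @param run_stats Set `FALSE` to skip the permutation contrasts (useful
#'   for simulation studies that only need the clustering).
#' @param verbose Print stage timings.
#' @return A `dfc_pipeline_result` list with every stage output plus
#'   `timings`.
#' @export
run_full_pipeline <- function(manifest, series, config = pipeline_config(),
                              out_dir = NULL, run_stats = TRUE,
                              verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- as_tibble(manifest)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      expr,
      error = function(e) abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
    )
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    if (verbose) message(sprintf("[%s] %.1fs", stage, timings[[stage]]))
    res
  }
  seed_for <- function(stage) derive_seed(config$seed, stage)

  qc <- clock("qc", qc_filter_fd(manifest, config$mean_fd_max, config$max_fd_max,
                                 rule = config$fd_rule))
  kept <- qc$kept

  patients <- filter(kept, .data$group == "patient")
  base_pool <- filter(kept, .data$group == "control_base")
  ica_ctrl <- filter(kept, .data$group == "control_ica")
  if (nrow(patients) == 0 || nrow(ica_ctrl) < 2) {
    abort("pipeline needs patients and at least two ICA-guidance controls after QC.")
  }
  matched <- clock("match", match_controls(patients, base_pool, seed = seed_for("match")))

  analysis_ids <- c(patients$subject_id, matched$subject_id)
  dfc_of <- function(ids) {
    lapply(setNames(ids, ids), function(sid) {
      sliding_window_fc(series[[sid]], config$window_length_s,
                        config$step_volumes, taper = config$taper)
    })
  }
  dfc_ica <- clock("dfc_ica", dfc_of(ica_ctrl$subject_id))
  dfc_main <- clock("dfc", dfc_of(analysis_ids))

  group_comp <- clock("group_ica",
                      fit_group_components(dfc_ica, K = config$n_components,
                                           seed = seed_for("group_ica")))
  subj_comp <- clock("subject_ica", lapply(dfc_main, function(d) {
    fit_subject_components(d, group_comp, lambda_ref = config$lambda_ref)
  }))

  features <- clock("features", extract_features(subj_comp))
  feat_cols <- setdiff(names(features), "subject_id")

  ctrl_features <- features |>
    filter(.data$subject_id %in% matched$subject_id) |>
    left_join(select(matched, "subject_id", "age"), by = "subject_id")
  pat_features <- features |>
    filter(.data$subject_id %in% patients$subject_id) |>
    left_join(select(patients, "subject_id", "age"), by = "subject_id")

  normative <- clock("normative",
                     fit_aggregate_normative(ctrl_features, feature_cols = feat_cols,
                                             n_folds = config$n_folds,
                                             taus = config$percentiles / 100,
                                             degree = config$normative_degree,
                                             n_boot = config$n_boot,
                                             seed = seed_for("normative")))
  zscores <- clock("deviations", score_cohort(pat_features, normative))
  ctrl_z <- clock("control_deviations", score_controls_heldout(normative, ctrl_features))

  selection <- clock("selection",
                     forward_select_features(zscores, k = config$k,
                                             runs = config$n_cluster_runs,
                                             threshold = config$selection_frequency_threshold,
                                             seed = seed_for("selection")))
  informative <- selection$informative_features
  if (length(informative) == 0) {
    warn("no feature exceeded the selection frequency threshold; clustering on all features.")
    informative <- feat_cols
  }
  zmat <- as_feature_matrix(zscores)[, informative, drop = FALSE]
  clusters <- clock("clustering",
                    cluster_ensemble(zmat, k = config$k,
                                     runs = config$n_cluster_runs,
                                     certainty_threshold = config$certainty_threshold,
                                     seed = seed_for("clustering")))

  stats_tables <- NULL
  if (run_stats) {
    stats_tables <- clock("stats", {
      assign_tbl <- clusters$assignments
      lab_of <- setNames(assign_tbl$final_label, assign_tbl$subject_id)
      retained_ids <- assign_tbl$subject_id[assign_tbl$retained]
      demo <- bind_rows(patients, matched[names(matched) != "matched_to"])
      z_all <- bind_rows(zscores, ctrl_z)
      contrast <- function(ids_a, ids_b, name) {
        ids <- c(ids_a, ids_b)
        zm <- z_all[match(ids, z_all$subject_id), , drop = FALSE]
        cov <- demo[match(ids, demo$subject_id), c("age", "sex", "education")]
        res <- permutation_ttest_adjusted(
          zm, group = rep(c("A", "B"), c(length(ids_a), length(ids_b))),
          covariates = cov, n_perm = config$n_permutations,
          alpha = config$alpha_edge, seed = seed_for(paste0("stats_", name))
        )
        mutate(as_tibble(res), contrast = name)
      }
      subtype_ids <- lapply(seq_len(config$k), function(cl) {
        intersect(retained_ids, names(lab_of)[lab_of == cl])
      })
      tabs <- list()
      for (cl in seq_len(config$k)) {
        if (length(subtype_ids[[cl]]) >= 2) {
          tabs[[length(tabs) + 1L]] <-
            contrast(matched$subject_id, subtype_ids[[cl]],
                     sprintf("control_vs_subtype%d", cl))
        }
      }
      if (config$k == 2 && all(lengths(subtype_ids[1:2]) >= 2)) {
        tabs[[length(tabs) + 1L]] <-
          contrast(subtype_ids[[1]], subtype_ids[[2]], "subtype1_vs_subtype2")
      }
      bind_rows(tabs)
    })
  }

  result <- structure(
    list(config = config, qc = qc, matched = matched,
         group_components = group_comp, subject_components = subj_comp,
         features = features, normative_model = normative,
         zscores = zscores, control_zscores = ctrl_z,
         selection = selection, clusters = clusters,
         stats = stats_tables,
         timings = tibble(stage = names(timings),
                          seconds = as.numeric(unlist(timings)))),
    class = "dfc_pipeline_result"
  )

  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.dfc_pipeline_result <- function(x, ...) {
  cat("<dfc_pipeline_result>\n")
  cat(sprintf("  %d patients, %d matched controls, K = %d, %d features\n",
              nrow(x$zscores), nrow(x$matched), x$config$n_components,
              length(setdiff(names(x$features), "subject_id"))))
  cat(sprintf("  informative features (%d): %s\n",
              length(x$selection$informative_features),
              paste(x$selection$informative_features, collapse = ", ")))
  print(x$clusters)
  invisible(x)
}

#' @export
#' @exportS3Method generics::tidy
tidy.dfc_pipeline_result <- function(x, ...) x$clusters$assignments

#' @export
#' @exportS3Method generics::glance
glance.dfc_pipeline_result <- function(x, ...) {
  bind_cols(glance(x$clusters),
            tibble(n_informative = length(x$selection$informative_features),
                   retained_variance = x$group_components$retained_variance))
}

# Persist the tabular pipeline outputs as plain text (CSV/JSON).
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$features, file.path(out_dir, "features.csv"), progress = FALSE)
  readr::write_csv(result$zscores, file.path(out_dir, "zscores.csv"), progress = FALSE)
  readr::write_csv(result$control_zscores, file.path(out_dir, "control_zscores.csv"),
                   progress = FALSE)
  readr::write_csv(result$clusters$assignments, file.path(out_dir, "labels.csv"),
                   progress = FALSE)
  if (!is.null(result$stats)) {
    readr::write_csv(result$stats, file.path(out_dir, "stats.csv"), progress = FALSE)
  }
  jsonlite::write_json(
    list(
      frequencies = result$selection$frequencies,
      informative_features = result$selection$informative_features,
      silhouette = result$clusters$silhouette,
      center_instability = result$clusters$center_instability,
      mean_stability = result$clusters$mean_stability,
      timings = result$timings
    ),
    file.path(out_dir, "results.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}
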