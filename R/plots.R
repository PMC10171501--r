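# ggplot2 visualisations for the main result types.

#' Plot selection frequencies
#'
#' Bar chart of per-feature selection frequencies with the informative
#' threshold marked.
#'
#' @param object A [forward_select_features()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.selection_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$frequency,
                                   fill = .data$informative)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey70"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "selection frequency",
                  title = sprintf("Wrapper selection over %d runs", object$runs)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' Plot a clustering ensemble
#'
#' Scatter of the first two informative features, coloured by final label;
#' low-certainty (excluded) subjects are hollow.
#'
#' @param object A [cluster_ensemble()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_ensemble <- function(object, ...) {
  X <- object$data
  df <- bind_cols(object$assignments,
                  tibble(x = X[, 1],
                         y = if (ncol(X) >= 2) X[, 2] else rep(0, nrow(X))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = factor(.data$final_label),
                                   shape = .data$retained)) +
    ggplot2::geom_point(size = 2, alpha = 0.85) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1), guide = "none") +
    ggplot2::labs(x = colnames(X)[1],
                  y = if (ncol(X) >= 2) colnames(X)[2] else NULL,
                  colour = "subtype",
                  title = sprintf("Repeated k-means (k = %d, %d runs)",
                                  object$k, object$runs)) +
    ggplot2::theme_minimal()
}

#' Plot fitted normative quantile curves
#'
#' The fitted 5th/50th/95th percentile curves over age with the training
#' points.
#'
#' @param object A [fit_quantile_curves()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.quantile_curves <- function(object, ...) {
  grid <- seq(object$age_range[1], object$age_range[2], length.out = 100)
  Q <- predict(object, grid)
  curves <- bind_rows(lapply(seq_along(object$taus), function(ti) {
    tibble(age = grid, value = Q[, ti],
           quantile = sprintf("q%g", 100 * object$taus[ti]))
  }))
  pts <- tibble(age = object$ages, value = object$values)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_point(data = pts, colour = "grey60", alpha = 0.5, size = 1) +
    ggplot2::geom_line(ggplot2::aes(linetype = .data$quantile), colour = "#b2182b") +
    ggplot2::labs(x = "age (years)", y = object$feature_name,
                  title = sprintf("Normative quantile curves: %s", object$feature_name)) +
    ggplot2::theme_minimal()
}

#' Plot permutation-test results
#'
#' Signed -log10 permutation p-values per feature with the alpha threshold.
#'
#' @param object A [permutation_ttest_adjusted()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.perm_test_result <- function(object, ...) {
  alpha <- attr(object, "alpha")
  df <- mutate(tidy(object),
               score = -log10(.data$p_perm) * .data$direction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$score,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-1, 1) * -log10(alpha), linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey70"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "signed -log10 p",
                  title = sprintf("Permutation tests (n = %d)", attr(object, "n_perm"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
}
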