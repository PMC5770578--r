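#' Plot mean cluster trajectories
#'
#' One line per cluster: the centroid trajectory over the 90 window days,
#' labelled with cluster size. The weekly periodicity (Sunday dips) is
#' visible as a 7-day ripple.
#'
#' @param object A [kmeans_longitudinal()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot traj_kmeans
#' @export
autoplot.traj_kmeans <- function(object, ...) {
  df <- tibble::tibble(
    cluster = factor(rep(seq_len(object$k), each = ncol(object$centroids))),
    day_index = rep(seq_len(ncol(object$centroids)), object$k),
    value = as.vector(t(object$centroids))
  )
  lab <- sprintf("cluster %d (n = %d)", seq_len(object$k), object$sizes)
  levels(df$cluster) <- lab
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day_index, y = .data$value,
                                   colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window day", y = "centroid value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Weekday periodicity of a daily feature
#'
#' Mean (with standard-error ribbon) of a daily feature by weekday across
#' all complete days, showing the weekly rhythm (typically a Sunday dip).
#'
#' @param features A [daily_features()] table.
#' @param feature Column to plot (default `"steps_total"`).
#' @return A ggplot object.
#' @export
plot_weekday_profile <- function(features, feature = "steps_total") {
  df <- dplyr::summarise(
    dplyr::group_by(features, .data$weekday),
    mean = mean(.data[[feature]], na.rm = TRUE),
    se = sd(.data[[feature]], na.rm = TRUE) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  df$weekday_lab <- factor(c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")[df$weekday + 1],
                           levels = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weekday_lab, y = .data$mean, group = 1)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se), alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = feature) +
    ggplot2::theme_minimal()
}

#' Per-participant mean activity distribution by group
#'
#' @param summary A [participant_summary()] tibble joined with a
#'   `disease_group` column (as in a study report's `summary`).
#' @param feature Summary column (default `"mvpa_min_day"`).
#' @return A ggplot object (violin + jitter).
#' @export
plot_group_distribution <- function(summary, feature = "mvpa_min_day") {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$disease_group,
                                        y = .data[[feature]])) +
    ggplot2::geom_violin(fill = "grey90") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = feature) +
    ggplot2::theme_minimal()
}

#' @method autoplot study_report
#' @export
autoplot.study_report <- function(object, ...) {
  if (!is.null(object$notice)) {
    at_abort("nothing to plot: the report is empty", "actitraj_input_error")
  }
  autoplot(object$cluster_model)
}
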