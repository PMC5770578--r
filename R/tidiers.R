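#' Tidy a trajectory K-means fit
#'
#' @param x A [kmeans_longitudinal()] fit.
#' @param ... Unused.
#' @return One row per cluster: size, proportion, within-cluster sum of
#'   squares, centroid grand mean.
#' @method tidy traj_kmeans
#' @export
tidy.traj_kmeans <- function(x, ...) {
  tibble::tibble(
    cluster = seq_len(x$k),
    size = x$sizes,
    proportion = x$sizes / sum(x$sizes),
    wss = x$wss_per_cluster,
    centroid_mean = rowMeans(x$centroids)
  )
}

#' @rdname tidy.traj_kmeans
#' @method glance traj_kmeans
#' @export
glance.traj_kmeans <- function(x, ...) {
  tibble::tibble(
    k = x$k, n = length(x$assignments),
    wss_total = x$wss_total,
    between = x$quality$between,
    calinski_harabasz = x$quality$calinski_harabasz,
    iterations = x$iterations, converged = x$converged,
    n_starts = x$n_starts
  )
}

#' Tidy a mixed-model group comparison
#'
#' @param x An [fit_group_lmm()] result.
#' @param ... Unused.
#' @return The fixed-effect table (term, estimate, std.error, df,
#'   statistic, p.value).
#' @method tidy lmm_fit
#' @export
tidy.lmm_fit <- function(x, ...) x$tidy

#' @rdname tidy.lmm_fit
#' @method glance lmm_fit
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(
    response = x$response, engine = x$engine,
    n_participants = x$n_participants, n_obs = x$n_obs,
    group_p = x$group_p, var_power_used = x$var_power_used,
    var_power_theta = x$var_power_theta, converged = x$converged
  )
}

#' Tidy an adjusted logistic regression
#'
#' @param x A `logistic_fit` (from [fit_who_logistic()] or
#'   [fit_low_cluster_logistic()]).
#' @param ... Unused.
#' @return Odds-ratio table with 95% Wald intervals; `or_units` gives the
#'   unit increase each OR is expressed for.
#' @method tidy logistic_fit
#' @export
tidy.logistic_fit <- function(x, ...) x$tidy

#' @rdname tidy.logistic_fit
#' @method glance logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, n = x$n, n_events = x$n_events,
    separation = x$separation, n_collinear = length(x$collinear)
  )
}
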