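#' K-means clustering of longitudinal activity trajectories
#'
#' Partitions whole per-participant trajectories (rows of a
#' [trajectory_matrix()], typically 90 days of one daily feature) into `k`
#' clusters by Lloyd's algorithm with plain Euclidean distance on the full
#' trajectory vector — the classic K-means-for-longitudinal-data approach.
#' The matrix must be complete (run [impute_missing_days()] first, or
#' restrict to complete cases). Multiple random starts are run and the
#' solution with the lowest total within-cluster sum of squares is kept.
#' Clusters are relabelled by ascending centroid grand mean, so cluster 1
#' is always the lowest-activity cluster.
#'
#' Numerical conventions: initial centroids are `k` distinct random rows;
#' a point equidistant from several centroids goes to the lowest cluster
#' index; a cluster that empties during iteration is re-seeded from the
#' point farthest from its centroid (counted in `n_reseeded`).
#'
#' @param x Complete numeric matrix (participants x days).
#' @param k Number of clusters (>= 1).
#' @param n_starts Number of random starts (default 20).
#' @param max_iter Maximum Lloyd iterations per start (default 100).
#' @param seed Optional integer seed for reproducible starts.
#' @param na_action `"fail"` (default: the matrix must be complete) or
#'   `"available"`: squared distances are computed over each trajectory's
#'   observed days and rescaled to the full window length
#'   (`ncol(x) / n_observed`), and centroids are means over the observed
#'   cells of member trajectories — available-case clustering of
#'   incomplete trajectories, used as the sensitivity counterpart of
#'   clustering the imputed matrix.
#' @return An object of class `traj_kmeans`: list with `assignments`
#'   (named integer vector), `centroids` (k x days), `sizes`, `wss_total`,
#'   `wss_trace` (of the winning start; non-increasing), `quality`
#'   (see [partition_quality()]), `iterations`, `converged`, `n_reseeded`,
#'   `k`, `n_starts`, `seed`.
#' @export
#' @examples
#' x <- rbind(matrix(5, 4, 10), matrix(50, 4, 10)) + rnorm(80, sd = 0.1)
#' rownames(x) <- paste0("P", 1:8)
#' km <- kmeans_longitudinal(x, k = 2, seed = 1)
#' km$sizes
kmeans_longitudinal <- function(x, k, n_starts = 20, max_iter = 100, seed = NULL,
                                na_action = c("fail", "available")) {
  x <- as.matrix(x)
  na_action <- match.arg(na_action)
  if (anyNA(x)) {
    if (na_action == "fail") {
      at_abort("trajectory matrix contains missing cells; impute or drop first",
               "actitraj_input_error")
    }
    if (any(rowSums(!is.na(x)) == 0)) {
      at_abort("a trajectory has no observed days", "actitraj_input_error")
    }
  }
  n <- nrow(x)
  if (k < 1 || k != floor(k)) at_abort("k must be a positive integer", "actitraj_input_error")
  if (k > n) {
    at_abort(sprintf("k = %d exceeds the number of participants (%d)", k, n),
             "actitraj_input_error")
  }
  if (n_starts < 1) at_abort("n_starts must be >= 1", "actitraj_input_error")
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- lloyd_once(x, k, max_iter)
    if (is.null(best) || fit$wss_total < best$wss_total - 1e-12) best <- fit
  }

  # canonical labels: ascending centroid grand mean
  ord <- order(rowMeans(best$centroids))
  relabel <- match(seq_len(k), ord)
  assignments <- relabel[best$assign]
  names(assignments) <- rownames(x) %||% as.character(seq_len(n))
  centroids <- best$centroids[ord, , drop = FALSE]
  rownames(centroids) <- paste0("cluster", seq_len(k))

  row_wss <- scaled_row_ss(x, centroids[assignments, , drop = FALSE])
  out <- list(
    assignments = assignments,
    centroids = centroids,
    sizes = as.integer(table(factor(assignments, levels = seq_len(k)))),
    wss_total = best$wss_total,
    wss_per_cluster = as.vector(rowsum(row_wss, assignments)),
    wss_trace = best$trace,
    iterations = best$iterations,
    converged = best$converged,
    n_reseeded = best$n_reseeded,
    k = k, n_starts = n_starts, seed = seed
  )
  class(out) <- "traj_kmeans"
  out$quality <- partition_quality(out, x)
  out
}

# one Lloyd run from a random initialization; handles incomplete rows by
# available-case distances (rescaled to the window length)
lloyd_once <- function(x, k, max_iter) {
  n <- nrow(x)
  has_na <- anyNA(x)
  mask <- if (has_na) !is.na(x) else NULL
  x0 <- if (has_na) ifelse(is.na(x), 0, x) else x
  seed_rows <- sample.int(n, k)
  cent <- x0[seed_rows, , drop = FALSE]
  if (has_na) { # fill unobserved coordinates of the seeds from column means
    cm <- colMeans(x, na.rm = TRUE)
    sm <- mask[seed_rows, , drop = FALSE]
    cent[!sm] <- matrix(cm, k, ncol(x0), byrow = TRUE)[!sm]
  }
  assign_old <- rep(0L, n)
  trace <- numeric(0)
  n_reseeded <- 0L
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- sqdist(x0, mask, cent)
    assign <- max.col(-d2, ties.method = "first") # equal distance: lowest index
    # re-seed an empty cluster from the farthest point and force it in
    # (forcing guarantees progress even when duplicate points tie)
    empty <- setdiff(seq_len(k), unique(assign))
    tries <- 0L
    while (length(empty) > 0 && tries < k + 5L) {
      dmin <- d2[cbind(seq_len(n), assign)]
      far <- which.max(dmin)
      cent[empty[1], ] <- x0[far, ]
      assign[far] <- empty[1]
      n_reseeded <- n_reseeded + 1L
      tries <- tries + 1L
      empty <- setdiff(seq_len(k), unique(assign))
    }
    cent <- centroid_update(x0, mask, assign, k, prev = cent)
    trace <- c(trace, sum(scaled_row_ss(x, cent[assign, , drop = FALSE])))
    if (identical(assign, assign_old)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    assign_old <- assign
  }
  list(assign = assign, centroids = cent, wss_total = trace[length(trace)],
       trace = trace, iterations = iter, converged = converged,
       n_reseeded = n_reseeded)
}

# squared Euclidean distances between rows of x and rows of cent; with an
# observation mask, distances use observed coordinates rescaled to the full
# trajectory length
sqdist <- function(x0, mask, cent) {
  if (is.null(mask)) {
    d2 <- outer(rowSums(x0^2), rowSums(cent^2), "+") - 2 * tcrossprod(x0, cent)
  } else {
    d2 <- rowSums(mask * x0^2) - 2 * tcrossprod(x0, cent) +
      mask %*% t(cent^2)
    d2 <- d2 * (ncol(x0) / rowSums(mask))
  }
  pmax(d2, 0)
}

# cluster means over observed cells; a column unobserved in a whole cluster
# falls back to the overall column mean, a fully empty cluster keeps its
# previous centroid
centroid_update <- function(x0, mask, assign, k, prev = NULL) {
  f <- factor(assign, levels = seq_len(k))
  sizes <- as.vector(table(f))
  if (is.null(mask)) {
    rs <- rowsum(x0, assign) # one row per non-empty cluster, sorted labels
    cent <- matrix(NA_real_, k, ncol(x0))
    present <- as.integer(rownames(rs))
    cent[present, ] <- rs / sizes[present]
    if (any(sizes == 0) && !is.null(prev)) {
      cent[sizes == 0, ] <- prev[sizes == 0, , drop = FALSE]
    }
    return(cent)
  }
  rsn <- rowsum(x0 * mask, assign)
  rsd <- rowsum(mask + 0, assign)
  num <- matrix(0, k, ncol(x0))
  den <- matrix(0, k, ncol(x0))
  present <- as.integer(rownames(rsn))
  num[present, ] <- rsn
  den[present, ] <- rsd
  cent <- num / den
  if (any(den == 0)) {
    overall <- colSums(x0 * mask) / colSums(mask)
    idx <- which(den == 0, arr.ind = TRUE)
    cent[idx] <- overall[idx[, 2]]
  }
  cent
}

# per-row (rescaled) squared distance to a matched matrix of centroids
scaled_row_ss <- function(x, cent_rows) {
  if (!anyNA(x)) return(rowSums((x - cent_rows)^2))
  mask <- !is.na(x)
  d <- ifelse(mask, (x - cent_rows)^2, 0)
  rowSums(d) * (ncol(x) / rowSums(mask))
}

#' Partition-quality scores for a trajectory clustering
#'
#' Computes the between-cluster dispersion B (size-weighted squared
#' distances of centroids to the grand mean trajectory), the within-cluster
#' dispersion W (total within-cluster sum of squares) and the
#' Calinski-Harabasz ratio `(B / (k - 1)) / (W / (n - k))` — higher is
#' better. For `k = 1` the ratio is undefined and returned as `NA`; for a
#' perfect partition (W = 0) it is `Inf`.
#'
#' @param model A [kmeans_longitudinal()] fit.
#' @param x The matrix the model was fitted to.
#' @return A one-row tibble: `k`, `n`, `between`, `within`,
#'   `calinski_harabasz`.
#' @export
partition_quality <- function(model, x) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- model$k
  grand <- colMeans(x, na.rm = TRUE)
  cent <- model$centroids
  sizes <- model$sizes
  between <- sum(sizes * rowSums((cent - matrix(grand, nrow = k, ncol = ncol(x),
                                                byrow = TRUE))^2))
  within <- sum(scaled_row_ss(x, cent[model$assignments, , drop = FALSE]))
  ch <- if (k <= 1 || n <= k) {
    NA_real_
  } else if (within == 0) {
    Inf
  } else {
    (between / (k - 1)) / (within / (n - k))
  }
  tibble::tibble(k = k, n = n, between = between, within = within,
                 calinski_harabasz = ch)
}

#' Select the number of trajectory clusters by partition quality
#'
#' Fits [kmeans_longitudinal()] for every `k` in `k_range` and returns the
#' model with the highest Calinski-Harabasz criterion. The full score table
#' is attached as attribute `scores`. If no candidate has a defined
#' criterion (e.g. `k_range = 1`), the first candidate is returned.
#'
#' @param x Complete trajectory matrix.
#' @param k_range Candidate cluster counts (default 2:5).
#' @param n_starts,max_iter,seed Passed to [kmeans_longitudinal()]; each
#'   candidate k uses a seed offset derived from `seed` so the whole scan
#'   is reproducible.
#' @return The selected `traj_kmeans` model with attribute `scores`.
#' @export
select_k <- function(x, k_range = 2:5, n_starts = 20, max_iter = 100, seed = NULL) {
  if (length(k_range) == 0) at_abort("k_range is empty", "actitraj_input_error")
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    fits[[i]] <- kmeans_longitudinal(
      x, k_range[i], n_starts = n_starts, max_iter = max_iter,
      seed = if (is.null(seed)) NULL else seed + i - 1L
    )
  }
  scores <- dplyr::bind_rows(lapply(fits, `[[`, "quality"))
  crit <- scores$calinski_harabasz
  pick <- if (all(is.na(crit))) 1L else which.max(crit)
  out <- fits[[pick]]
  attr(out, "scores") <- scores
  out
}

#' Characterize trajectory clusters
#'
#' Per-cluster sizes, cohort proportions, mean (SD) of the clustered
#' feature, and covariate summaries (age, BMI, sex, disease group,
#' disease-activity scores by subgroup). The lowest-activity cluster
#' (label 1) is flagged.
#'
#' @param model A [kmeans_longitudinal()] fit.
#' @param summary A [participant_summary()] tibble.
#' @param covariates Covariate table keyed by `participant_id`.
#' @param feature Summary column to profile (default `"mvpa_min_day"`).
#' @return A tibble with one row per cluster.
#' @export
profile_clusters <- function(model, summary, covariates,
                             feature = "mvpa_min_day") {
  ids <- names(model$assignments)
  missing_cov <- setdiff(ids, covariates$participant_id)
  if (length(missing_cov) > 0) {
    at_abort(sprintf("participant %s has no covariate row", missing_cov[1]),
             "actitraj_input_error")
  }
  df <- tibble::tibble(participant_id = ids,
                       cluster = as.integer(model$assignments))
  df <- dplyr::left_join(df, summary, by = "participant_id")
  new_cols <- c("participant_id", setdiff(names(covariates), names(df)))
  df <- dplyr::left_join(df, covariates[, new_cols], by = "participant_id")
  if (!feature %in% names(df)) {
    at_abort(sprintf("feature `%s` not found in participant summary", feature),
             "actitraj_input_error")
  }
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$cluster),
    n = dplyr::n(),
    feature_mean = mean(.data[[feature]]),
    feature_sd = sd(.data[[feature]]),
    age_mean = mean(.data$age),
    bmi_mean = mean(.data$bmi),
    female_frac = mean(.data$sex == "female"),
    axspa_frac = mean(.data$disease_group == "axSpA"),
    biologic_frac = mean(.data$biologic),
    das28_mean = mean(.data$das28, na.rm = TRUE),
    basdai_mean = mean(.data$basdai, na.rm = TRUE),
    .groups = "drop"
  )
  out <- dplyr::mutate(out,
                       proportion = .data$n / sum(.data$n),
                       is_low = .data$cluster == 1L)
  out$feature <- feature
  dplyr::relocate(out, "cluster", "n", "proportion", "is_low")
}

#' @export
print.traj_kmeans <- function(x, ...) {
  cat(sprintf("<traj_kmeans> k = %d, n = %d, total WSS = %.1f\n",
              x$k, length(x$assignments), x$wss_total))
  cat(sprintf("  sizes: %s | Calinski-Harabasz: %s\n",
              paste(x$sizes, collapse = "/"),
              format(x$quality$calinski_harabasz, digits = 4)))
  invisible(x)
}
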