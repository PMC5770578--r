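#' Build a participants-by-days trajectory matrix of one feature
#'
#' Spreads one daily feature into a matrix with one row per participant and
#' one column per window day (1..90). Cells for days that are not complete
#' (missing or partial days) are `NA`; they are exactly the non-full days.
#'
#' @param features A [daily_features()] table (complete days only).
#' @param feature Column to spread (default `"mvpa_minutes"`).
#' @param participants Optional character vector fixing row order and
#'   membership; defaults to the participants present in `features`.
#' @param n_days Number of window days (default 90).
#' @return A numeric matrix of class `trajectory_matrix` with participant
#'   ids as row names and attribute `feature`.
#' @export
trajectory_matrix <- function(features, feature = "mvpa_minutes",
                              participants = NULL, n_days = 90) {
  if (!feature %in% names(features)) {
    at_abort(sprintf("feature `%s` not found in daily features", feature),
             "actitraj_input_error")
  }
  participants <- participants %||% sort(unique(features$participant_id))
  m <- matrix(NA_real_, nrow = length(participants), ncol = n_days,
              dimnames = list(participants, paste0("d", seq_len(n_days))))
  ri <- match(features$participant_id, participants)
  keep <- !is.na(ri) & features$day_index >= 1 & features$day_index <= n_days
  m[cbind(ri[keep], features$day_index[keep])] <- features[[feature]][keep]
  structure(m, feature = feature, class = c("trajectory_matrix", "matrix", "array"))
}

#' Impute missing trajectory days by same-weekday means
#'
#' Replaces each missing cell by the mean of the participant's observed
#' values on the same weekday (windows start on Mondays, so column `d`
#' falls on weekday `(d - 1) %% 7`). Observed cells are left bit-identical.
#' A participant with no observed instance of some weekday falls back to
#' their overall observed mean; such fallbacks are recorded in the
#' `fallbacks` attribute for audit.
#'
#' @param x A [trajectory_matrix()] (may contain `NA`s; every row must have
#'   at least one observed value).
#' @return A complete `trajectory_matrix`; attributes `imputed` (logical
#'   mask of imputed cells) and `fallbacks` (tibble participant/weekday).
#' @export
impute_missing_days <- function(x) {
  stopifnot(inherits(x, "trajectory_matrix") || is.matrix(x))
  if (any(rowSums(!is.na(x)) == 0)) {
    bad <- rownames(x)[rowSums(!is.na(x)) == 0][1]
    at_abort(sprintf("participant %s has no observed days to impute from", bad),
             "actitraj_input_error")
  }
  wd <- (seq_len(ncol(x)) - 1L) %% 7L
  out <- x
  fallbacks <- list()
  for (i in seq_len(nrow(x))) {
    row <- x[i, ]
    miss <- is.na(row)
    if (!any(miss)) next
    overall <- mean(row, na.rm = TRUE)
    for (w in unique(wd[miss])) {
      obs <- row[wd == w & !miss]
      if (length(obs) == 0) {
        fill <- overall
        fallbacks[[length(fallbacks) + 1L]] <-
          tibble::tibble(participant_id = rownames(x)[i] %||% as.character(i),
                         weekday = w)
      } else {
        fill <- mean(obs)
      }
      out[i, wd == w & miss] <- fill
    }
  }
  attr(out, "imputed") <- is.na(x)
  attr(out, "fallbacks") <- if (length(fallbacks)) {
    dplyr::bind_rows(fallbacks)
  } else {
    tibble::tibble(participant_id = character(), weekday = integer())
  }
  out
}
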