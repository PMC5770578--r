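#' Daily activity features from one 1440-minute day vector
#'
#' Derives the daily activity patterns for a single full day given as a
#' 1440-slot step vector: total steps, morning-step fraction (steps between
#' 00:00 and 12:00 over total steps), active minutes (cadence at or above
#' the rest threshold), MVPA minutes, vigorous minutes, and steps
#' accumulated in MVPA minutes. All threshold comparisons are inclusive.
#'
#' @param steps_by_minute Integer vector of length 1440.
#' @param thresholds A [cadence_thresholds()] object.
#' @param require_full If `TRUE` (default) calling this on a day that fails
#'   the full-day rule is a contract violation and errors.
#' @return A one-row tibble of features. `morning_fraction` is `NA` for a
#'   zero-step day (0/0 is undefined; such a day cannot be full anyway).
#' @export
#' @examples
#' day <- integer(1440)
#' day[(8 * 60 + 1):(8 * 60 + 30)] <- 110 # 08:00-08:29 at 110 steps/min
#' day[(14 * 60 + 1):(15 * 60)] <- 50     # 14:00-14:59 at 50 steps/min
#' minute_features(day)
minute_features <- function(steps_by_minute, thresholds = cadence_thresholds(),
                            require_full = TRUE) {
  stopifnot(length(steps_by_minute) == 1440)
  if (require_full && !is_full_day(steps_by_minute)) {
    at_abort("daily features requested for a day failing the full-day rule",
             "actitraj_contract_error")
  }
  total <- sum(steps_by_minute)
  morning <- sum(steps_by_minute[1:720])
  tibble::tibble(
    steps_total = as.integer(total),
    morning_fraction = if (total > 0) morning / total else NA_real_,
    active_minutes = sum(steps_by_minute >= thresholds$rest),
    mvpa_minutes = sum(steps_by_minute >= thresholds$mvpa),
    vigorous_minutes = sum(steps_by_minute >= thresholds$vigorous),
    mvpa_steps = as.integer(sum(steps_by_minute[steps_by_minute >= thresholds$mvpa]))
  )
}

#' Daily activity features for every complete day of a cohort
#'
#' Applies the cadence definitions to every full day of an assembled
#' cohort. Only complete days are scored; partial and missing days are
#' omitted (they reappear as missing cells in [trajectory_matrix()]).
#'
#' @param assembled An [assemble_days()] result (typically the `analyzable`
#'   element of [filter_adherent()]).
#' @param thresholds A [cadence_thresholds()] object.
#' @return A tibble with one row per participant-complete-day:
#'   `participant_id`, `day_index`, `date`, `weekday`, `steps_total`,
#'   `morning_fraction`, `active_minutes`, `mvpa_minutes`,
#'   `vigorous_minutes`, `mvpa_steps`. Thresholds are attached as an
#'   attribute.
#' @export
daily_features <- function(assembled, thresholds = cadence_thresholds()) {
  stopifnot(inherits(assembled, "assembled_cohort"))
  full <- assembled$days[assembled$days$full_day,
                         c("participant_id", "day_index", "date", "weekday")]
  m <- dplyr::semi_join(assembled$minutes, full,
                        by = c("participant_id", "day_index"))
  feats <- dplyr::summarise(
    dplyr::group_by(m, .data$participant_id, .data$day_index),
    steps_total = sum(.data$steps),
    morning_steps = sum(.data$steps[.data$minute_of_day < 720]),
    active_minutes = sum(.data$steps >= thresholds$rest),
    mvpa_minutes = sum(.data$steps >= thresholds$mvpa),
    vigorous_minutes = sum(.data$steps >= thresholds$vigorous),
    mvpa_steps = sum(.data$steps[.data$steps >= thresholds$mvpa]),
    .groups = "drop"
  )
  feats$morning_fraction <- ifelse(feats$steps_total > 0,
                                   feats$morning_steps / feats$steps_total,
                                   NA_real_)
  out <- dplyr::left_join(full, feats, by = c("participant_id", "day_index"))
  out <- out[, c("participant_id", "day_index", "date", "weekday",
                 "steps_total", "morning_fraction", "active_minutes",
                 "mvpa_minutes", "vigorous_minutes", "mvpa_steps")]
  attr(out, "thresholds") <- thresholds
  out
}

#' Per-participant activity summary over complete days
#'
#' Averages the daily features over each participant's complete days and
#' derives weekly MVPA. Two weekly aggregations are exposed: the default
#' multiplies the participant's daily MVPA mean by 7; `"calendar_week"`
#' scales each window week's observed MVPA to 7 days and averages across
#' weeks (the two differ when missingness is uneven across weeks).
#'
#' @param features A [daily_features()] table (or the `daily` element of a
#'   day-resolution cohort restricted to full days).
#' @param weekly Weekly MVPA aggregation: `"daily_mean_x7"` or
#'   `"calendar_week"`.
#' @return A tibble with one row per participant: `n_days`, `steps_day`,
#'   `active_min_day`, `mvpa_min_day`, `vigorous_min_day`,
#'   `morning_fraction`, `mvpa_min_week`, `vigorous_min_week`.
#' @export
participant_summary <- function(features, weekly = c("daily_mean_x7", "calendar_week")) {
  weekly <- match.arg(weekly)
  if (nrow(features) == 0) {
    at_abort("no complete days to summarise", "actitraj_contract_error")
  }
  out <- dplyr::summarise(
    dplyr::group_by(features, .data$participant_id),
    n_days = dplyr::n(),
    steps_day = mean(.data$steps_total),
    active_min_day = mean(.data$active_minutes),
    mvpa_min_day = mean(.data$mvpa_minutes),
    vigorous_min_day = mean(.data$vigorous_minutes),
    morning_fraction = mean(.data$morning_fraction, na.rm = TRUE),
    .groups = "drop"
  )
  if (weekly == "daily_mean_x7") {
    out$mvpa_min_week <- out$mvpa_min_day * 7
    out$vigorous_min_week <- out$vigorous_min_day * 7
  } else {
    wk <- dplyr::summarise(
      dplyr::group_by(dplyr::mutate(features, week = (.data$day_index - 1) %/% 7),
                      .data$participant_id, .data$week),
      mvpa_wk = sum(.data$mvpa_minutes) * 7 / dplyr::n(),
      vig_wk = sum(.data$vigorous_minutes) * 7 / dplyr::n(),
      .groups = "drop"
    )
    wk <- dplyr::summarise(dplyr::group_by(wk, .data$participant_id),
                           mvpa_min_week = mean(.data$mvpa_wk),
                           vigorous_min_week = mean(.data$vig_wk),
                           .groups = "drop")
    out <- dplyr::left_join(out, wk, by = "participant_id")
  }
  out
}

#' WHO physical-activity recommendation status
#'
#' Scores each participant's summary against the physical-activity
#' recommendations: at least 150 min/week of moderate-to-vigorous activity,
#' at least 75 min/week of vigorous activity, and the step-count
#' translations of 10,000 and 7,000 steps/day. All comparisons inclusive.
#'
#' @param summary A [participant_summary()] tibble.
#' @param mvpa_week,vigorous_week,steps10k,steps7k Thresholds.
#' @return The summary tibble with logical columns `who_mvpa_met`,
#'   `who_vigorous_met`, `who_met` (either criterion), `steps10k_met`,
#'   `steps7k_met`.
#' @export
who_status <- function(summary, mvpa_week = 150, vigorous_week = 75,
                       steps10k = 10000, steps7k = 7000) {
  dplyr::mutate(
    summary,
    who_mvpa_met = .data$mvpa_min_week >= mvpa_week,
    who_vigorous_met = .data$vigorous_min_week >= vigorous_week,
    who_met = .data$who_mvpa_met | .data$who_vigorous_met,
    steps10k_met = .data$steps_day >= steps10k,
    steps7k_met = .data$steps_day >= steps7k
  )
}

#' Cohort adherence to the tracker
#'
#' Summarises wearing behaviour over all included participants (analyzable
#' or not): a day counts as worn when it has at least one record, not only
#' when it is a full day.
#'
#' @param assembled An [assemble_days()] result over every included
#'   participant.
#' @param end_window Number of trailing window days used for "still wearing
#'   at the end" (default 7).
#' @return A one-row tibble: `n_participants`, `mean_days_worn`,
#'   `sd_days_worn`, `mean_pct_days_worn`, `sd_pct_days_worn`,
#'   `frac_worn_80plus` (fraction wearing at least 80 of 90 days),
#'   `frac_wearing_at_end`. The per-participant table is attached as
#'   attribute `by_participant`.
#' @export
adherence_summary <- function(assembled, end_window = 7) {
  stopifnot(inherits(assembled, "assembled_cohort"))
  per <- assembled$participants
  last_days <- assembled$days[assembled$days$day_index > 90 - end_window, ]
  at_end <- dplyr::summarise(dplyr::group_by(last_days, .data$participant_id),
                             wearing_at_end = any(.data$any_record),
                             .groups = "drop")
  per <- dplyr::left_join(per, at_end, by = "participant_id")
  out <- tibble::tibble(
    n_participants = nrow(per),
    mean_days_worn = mean(per$n_days_worn),
    sd_days_worn = sd(per$n_days_worn),
    mean_pct_days_worn = mean(per$n_days_worn / 90) * 100,
    sd_pct_days_worn = sd(per$n_days_worn / 90) * 100,
    frac_worn_80plus = mean(per$n_days_worn >= 80),
    frac_wearing_at_end = mean(per$wearing_at_end)
  )
  attr(out, "by_participant") <- per
  out
}
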