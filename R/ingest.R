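#' Build the 90-day observation window for one activation date
#'
#' The window spans 90 consecutive calendar days beginning on the first
#' Monday strictly after the device-activation date (an activation on a
#' Monday therefore starts the following Monday). Because every window
#' starts on a Monday, `weekday` is simply `(day_index - 1) %% 7`
#' (0 = Monday, ..., 6 = Sunday) for every participant.
#'
#' @param activation_date A `Date` (or string coercible to one).
#' @return A tibble with 90 rows: `day_index` (1..90), `date`, `weekday`;
#'   the start date is also attached as attribute `start_date`.
#' @export
#' @examples
#' w <- build_window(as.Date("2016-01-06")) # a Wednesday
#' w$date[1] # Monday 2016-01-11
build_window <- function(activation_date) {
  activation_date <- as.Date(activation_date)
  if (length(activation_date) != 1 || is.na(activation_date)) {
    at_abort("activation_date must be a single valid date", "actitraj_input_error")
  }
  u <- as.integer(format(activation_date, "%u")) # 1 = Monday .. 7 = Sunday
  start <- activation_date + (8L - u)
  out <- tibble::tibble(
    day_index = 1:90,
    date = start + 0:89,
    weekday = (0:89) %% 7L
  )
  attr(out, "start_date") <- start
  out
}

#' Read one participant's minute-level step stream
#'
#' Parses a delimited file with header `timestamp,steps`: ISO-8601 minute
#' timestamps and non-negative integer step counts. Records are returned
#' sorted; duplicate minutes, negative counts and malformed rows are
#' rejected with informative errors.
#'
#' @param path Path to the stream file.
#' @param participant_id Identifier to attach; defaults to the file name
#'   without extension.
#' @return A tibble (`participant_id`, `timestamp`, `steps`) of class
#'   `step_stream`.
#' @export
read_step_stream <- function(path, participant_id = NULL) {
  if (!file.exists(path)) {
    at_abort(sprintf("stream file not found: %s", path), "actitraj_io_error")
  }
  participant_id <- participant_id %||% sub("\\.[^.]*$", "", basename(path))
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(timestamp = readr::col_datetime(),
                            steps = readr::col_double()),
    locale = readr::locale(tz = "UTC"), progress = FALSE
  ))
  pr <- readr::problems(raw)
  if (nrow(pr) > 0) { # problems() reports one-based file lines incl. header
    at_abort(sprintf("malformed row in %s at line %d: expected %s, got %s",
                     path, pr$row[1], pr$expected[1], pr$actual[1]),
             "actitraj_parse_error")
  }
  validate_stream(raw, participant_id)
}

validate_stream <- function(records, participant_id) {
  if (nrow(records) > 0) {
    if (any(is.na(records$timestamp))) {
      at_abort(sprintf("stream %s: unparseable timestamp", participant_id),
               "actitraj_parse_error")
    }
    if (any(is.na(records$steps) | records$steps < 0)) {
      bad <- which(is.na(records$steps) | records$steps < 0)[1]
      at_abort(sprintf("stream %s: negative or missing step count at %s",
                       participant_id, format(records$timestamp[bad])),
               "actitraj_parse_error")
    }
    if (any(records$steps != floor(records$steps))) {
      at_abort(sprintf("stream %s: non-integer step count", participant_id),
               "actitraj_parse_error")
    }
    records <- dplyr::arrange(records, .data$timestamp)
    minute <- floor(as.numeric(records$timestamp) / 60)
    dup <- duplicated(minute)
    if (any(dup)) {
      at_abort(sprintf("stream %s: duplicate record for minute %s",
                       participant_id,
                       format(records$timestamp[which(dup)[1]], tz = "UTC")),
               "actitraj_parse_error")
    }
  }
  out <- tibble::tibble(
    participant_id = rep(participant_id, nrow(records)),
    timestamp = records$timestamp,
    steps = as.integer(records$steps)
  )
  class(out) <- c("step_stream", class(out))
  out
}

#' Decide whether a day of minute records is a "full" day
#'
#' A day is full when at least 8 hours (480 minutes) elapse between the
#' first and the last minute with recorded steps. A day with no steps, or
#' with a single stepped minute (span 0), is not full.
#'
#' @param steps_by_minute Numeric vector of length 1440 (minute 1 =
#'   00:00-00:01) of step counts for one calendar day.
#' @param min_span Minimum first-to-last-step span in minutes (default 480).
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' day <- integer(1440)
#' day[8 * 60 + 1] <- 50; day[20 * 60 + 1] <- 50
#' is_full_day(day) # span 720 min -> TRUE
is_full_day <- function(steps_by_minute, min_span = 480) {
  stopifnot(length(steps_by_minute) == 1440, all(steps_by_minute >= 0, na.rm = TRUE))
  idx <- which(steps_by_minute > 0)
  if (length(idx) == 0) return(FALSE)
  (max(idx) - min(idx)) >= min_span
}

#' Assemble minute records into window days for a whole cohort
#'
#' Maps each in-window record of each participant to its `day_index` /
#' minute-of-day slot, discards (and counts) records outside the 90-day
#' observation window, and computes per-day validity: whether any record
#' exists, the first/last stepped minute, the span, and the full-day flag.
#'
#' @param steps Minute records: a tibble with `participant_id`, `timestamp`
#'   (POSIXct) and `steps`, e.g. the `steps` element of a minute-resolution
#'   [generate_cohort()] cohort, or rows bound from [read_step_stream()].
#' @param covariates Covariate table with `participant_id` and
#'   `activation_date` (used to build each participant's window).
#' @param min_span Full-day rule: minimum first-to-last-step span (minutes).
#' @return An object of class `assembled_cohort`: list with
#'   `days` (participant x 90 grid: `status` fields, `steps_total`,
#'   `full_day`), `minutes` (in-window records with `day_index` and
#'   `minute_of_day`), `participants` (per-participant window start,
#'   `n_complete_days`, `n_days_worn`, `out_of_window_records`), and
#'   `covariates`.
#' @export
assemble_days <- function(steps, covariates, min_span = 480) {
  stopifnot(all(c("participant_id", "timestamp", "steps") %in% names(steps)),
            all(c("participant_id", "activation_date") %in% names(covariates)))
  ids <- covariates$participant_id
  if (anyDuplicated(ids)) {
    at_abort("duplicate participant_id in covariate table", "actitraj_input_error")
  }

  windows <- dplyr::bind_rows(lapply(seq_along(ids), function(i) {
    w <- build_window(covariates$activation_date[i])
    w$participant_id <- ids[i]
    w
  }))

  recs <- dplyr::mutate(
    steps,
    date = as.Date(.data$timestamp, tz = "UTC"),
    minute_of_day = as.integer(format(.data$timestamp, "%H", tz = "UTC")) * 60L +
      as.integer(format(.data$timestamp, "%M", tz = "UTC"))
  )
  inwin <- dplyr::inner_join(recs, windows, by = c("participant_id", "date"))
  n_in <- dplyr::count(inwin, .data$participant_id, name = "n_in")
  n_all <- dplyr::count(steps, .data$participant_id, name = "n_all")

  per_day <- dplyr::summarise(
    dplyr::group_by(inwin, .data$participant_id, .data$day_index),
    steps_total = sum(.data$steps),
    first_step_minute = ifelse(any(.data$steps > 0),
                               min(.data$minute_of_day[.data$steps > 0]), NA_integer_),
    last_step_minute = ifelse(any(.data$steps > 0),
                              max(.data$minute_of_day[.data$steps > 0]), NA_integer_),
    .groups = "drop"
  )

  days <- dplyr::left_join(windows, per_day, by = c("participant_id", "day_index"))
  days <- dplyr::mutate(
    days,
    any_record = !is.na(.data$steps_total),
    steps_total = dplyr::coalesce(.data$steps_total, 0L),
    span_minutes = .data$last_step_minute - .data$first_step_minute,
    full_day = .data$any_record & !is.na(.data$span_minutes) &
      .data$span_minutes >= min_span
  )
  days <- days[, c("participant_id", "day_index", "date", "weekday", "any_record",
                   "steps_total", "first_step_minute", "last_step_minute",
                   "span_minutes", "full_day")]

  participants <- dplyr::summarise(
    dplyr::group_by(days, .data$participant_id),
    n_complete_days = sum(.data$full_day),
    n_days_worn = sum(.data$any_record),
    .groups = "drop"
  )
  participants <- dplyr::left_join(participants, n_all, by = "participant_id")
  participants <- dplyr::left_join(participants, n_in, by = "participant_id")
  participants <- dplyr::mutate(
    participants,
    out_of_window_records = dplyr::coalesce(.data$n_all, 0L) -
      dplyr::coalesce(.data$n_in, 0L)
  )
  participants <- dplyr::left_join(
    participants,
    dplyr::summarise(dplyr::group_by(windows, .data$participant_id),
                     start_date = min(.data$date), .groups = "drop"),
    by = "participant_id"
  )
  participants <- participants[, c("participant_id", "start_date",
                                   "n_complete_days", "n_days_worn",
                                   "out_of_window_records")]

  structure(
    list(days = days,
         minutes = inwin[, c("participant_id", "day_index", "date", "weekday",
                             "minute_of_day", "steps")],
         participants = participants,
         covariates = covariates,
         min_span = min_span),
    class = "assembled_cohort"
  )
}

#' @export
print.assembled_cohort <- function(x, ...) {
  cat(sprintf("<assembled_cohort> %d participants, %d in-window minute records\n",
              nrow(x$participants), nrow(x$minutes)))
  cat(sprintf("  complete days: median %s of 90 (full-day rule: span >= %d min)\n",
              median(x$participants$n_complete_days), x$min_span))
  invisible(x)
}

#' Materialize one calendar day as a 1440-slot step vector
#'
#' @param assembled An [assemble_days()] result.
#' @param participant_id Participant to extract.
#' @param day_index Window day (1..90).
#' @return Integer vector of length 1440 (minute 1 = 00:00).
#' @export
day_profile <- function(assembled, participant_id, day_index) {
  stopifnot(inherits(assembled, "assembled_cohort"))
  m <- assembled$minutes
  m <- m[m$participant_id == participant_id & m$day_index == day_index, ]
  out <- integer(1440)
  out[m$minute_of_day + 1L] <- m$steps
  out
}

#' Partition a cohort by the adherence threshold
#'
#' Splits assembled participants into the analyzable set (at least
#' `min_days` complete days out of 90) and the excluded set. Both sets are
#' returned; the excluded set still feeds adherence reporting.
#'
#' @param assembled An [assemble_days()] result.
#' @param min_days Minimum number of complete (full) days (default 60,
#'   boundary inclusive).
#' @return A list with `analyzable` and `excluded` (both `assembled_cohort`
#'   objects restricted to the respective participants) and `summary`
#'   (tibble of counts: included, analyzable, excluded).
#' @export
filter_adherent <- function(assembled, min_days = 60) {
  stopifnot(inherits(assembled, "assembled_cohort"))
  ok_ids <- assembled$participants$participant_id[
    assembled$participants$n_complete_days >= min_days]
  subset_cohort <- function(ids) {
    structure(
      list(days = assembled$days[assembled$days$participant_id %in% ids, ],
           minutes = assembled$minutes[assembled$minutes$participant_id %in% ids, ],
           participants = assembled$participants[
             assembled$participants$participant_id %in% ids, ],
           covariates = assembled$covariates[
             assembled$covariates$participant_id %in% ids, ],
           min_span = assembled$min_span),
      class = "assembled_cohort"
    )
  }
  all_ids <- assembled$participants$participant_id
  list(
    analyzable = subset_cohort(ok_ids),
    excluded = subset_cohort(setdiff(all_ids, ok_ids)),
    summary = tibble::tibble(
      included = length(all_ids),
      analyzable = length(ok_ids),
      excluded = length(all_ids) - length(ok_ids),
      min_days = min_days
    )
  )
}
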