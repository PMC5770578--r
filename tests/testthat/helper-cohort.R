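# shared fixture builders and independent oracles (built in code, no files)

# minute records from compact (date, minute-of-day, steps) triples
make_steps <- function(participant_id, date, minute, steps) {
  tibble::tibble(
    participant_id = participant_id,
    timestamp = as.POSIXct(as.Date(date), tz = "UTC") + minute * 60,
    steps = as.integer(steps)
  )
}

# minimal covariate table: one row per participant
make_covariates <- function(ids, activation = as.Date("2016-01-06")) {
  n <- length(ids)
  tibble::tibble(
    participant_id = ids,
    disease_group = rep_len(c("RA", "axSpA"), n),
    sex = rep_len(c("female", "male"), n),
    age = seq(30, 60, length.out = n),
    bmi = seq(21, 31, length.out = n),
    disease_duration = rep_len(c(4, 12), n),
    biologic = rep_len(c(TRUE, FALSE), n),
    employed = rep_len(c(TRUE, TRUE, FALSE), n),
    ptga = rep_len(c(2, 5), n),
    das28 = rep_len(c(2.1, NA), n),
    basdai = rep_len(c(NA, 3.0), n),
    activation_date = rep_len(activation, n)
  )
}

# a 1440-minute day vector from (start_minute, length, cadence) blocks
make_day <- function(...) {
  day <- integer(1440)
  for (blk in list(...)) {
    idx <- blk[1] + seq_len(blk[2]) - 1L
    day[idx + 1L] <- blk[3]
  }
  day
}

# a participant whose records cover `dates` with a wide-span full day
full_day_records <- function(id, dates, morning_steps = 60, evening_steps = 80) {
  dplyr::bind_rows(lapply(dates, function(d) {
    make_steps(id, rep(as.character(d), 2), c(8 * 60, 20 * 60),
               c(morning_steps, evening_steps))
  }))
}

# brute-force K-means oracle: minimal within-cluster sum of squares over
# every surjective assignment of n points to k clusters (enumeration)
brute_force_wss <- function(x, k) {
  n <- nrow(x)
  stopifnot(k^n <= 2e5)
  best <- Inf
  for (code in 0:(k^n - 1)) {
    a <- integer(n)
    c0 <- code
    for (i in seq_len(n)) {
      a[i] <- c0 %% k
      c0 <- c0 %/% k
    }
    if (length(unique(a)) < k) next
    wss <- 0
    for (j in 0:(k - 1)) {
      xj <- x[a == j, , drop = FALSE]
      wss <- wss + sum(sweep(xj, 2, colMeans(xj))^2)
    }
    if (wss < best) best <- wss
  }
  best
}

# day-resolution cohort reduced to a complete-day feature table
day_features <- function(cohort) {
  f <- cohort$daily[cohort$daily$full_day, ]
  f[!is.na(f$steps_total), ]
}

# adherent ids of a day-resolution cohort
adherent_ids <- function(cohort, min_days = 60) {
  cnt <- table(cohort$daily$participant_id[cohort$daily$full_day])
  names(cnt)[cnt >= min_days]
}

# ground-truth class labels aligned to a model's assignment names
gt_classes <- function(cohort, model) {
  gt <- cohort$ground_truth
  gt$class[match(names(model$assignments), gt$participant_id)]
}
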