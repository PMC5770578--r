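test_that("daily features match the hand-computed oracle", {
  # 30 min at 110 steps/min from 08:00 + 60 min at 50 steps/min from 14:00:
  # steps 30*110 + 60*50 = 6300; morning steps 3300; active 90; mvpa 30
  day <- make_day(c(8 * 60, 30, 110), c(14 * 60, 60, 50))
  f <- minute_features(day, require_full = FALSE) # span 08:00-14:59 < 8 h
  expect_equal(f$steps_total, 6300L)
  expect_equal(f$mvpa_minutes, 30)
  expect_equal(f$active_minutes, 90)
  expect_equal(f$vigorous_minutes, 0)
  expect_equal(f$morning_fraction, 3300 / 6300)
  expect_equal(f$mvpa_steps, 3300L)
})

test_that("a single 25-step morning minute gives one active minute", {
  day <- make_day(c(6 * 60, 1, 25))
  f <- minute_features(day, require_full = FALSE)
  expect_equal(f$steps_total, 25L)
  expect_equal(f$active_minutes, 1)
  expect_equal(f$mvpa_minutes, 0)
  expect_equal(f$morning_fraction, 1.0)
})

test_that("cadence thresholds are inclusive at the boundary", {
  day <- make_day(c(8 * 60, 1, 100), c(9 * 60, 1, 99), c(10 * 60, 1, 130),
                  c(11 * 60, 1, 20), c(12 * 60, 1, 19), c(20 * 60, 1, 5))
  f <- minute_features(day)
  expect_equal(f$mvpa_minutes, 2)     # 100 and 130 both count
  expect_equal(f$vigorous_minutes, 1) # only 130
  expect_equal(f$active_minutes, 4)   # 100, 99, 130, 20
})

test_that("requesting features for a non-full day violates the contract", {
  day <- make_day(c(10 * 60, 30, 80))
  expect_error(minute_features(day), "full-day rule")
})

test_that("cohort daily features respect the ordering invariants", {
  co <- generate_cohort(cohort_spec(n_participants = 10, seed = 30))
  asm <- assemble_days(co$steps, co$covariates)
  f <- daily_features(asm)
  expect_true(all(f$vigorous_minutes <= f$mvpa_minutes))
  expect_true(all(f$mvpa_minutes <= f$active_minutes))
  expect_true(all(f$active_minutes <= 1440))
  expect_true(all(f$mvpa_steps <= f$steps_total))
  expect_true(all(f$morning_fraction >= 0 & f$morning_fraction <= 1, na.rm = TRUE))
  # features exist exactly for full days
  expect_equal(nrow(f), sum(asm$days$full_day))
  # and agree with the single-day reference implementation on a sample
  pick <- f[c(1, nrow(f) %/% 2, nrow(f)), ]
  for (i in seq_len(nrow(pick))) {
    ref <- minute_features(day_profile(asm, pick$participant_id[i],
                                       pick$day_index[i]))
    expect_equal(pick$steps_total[i], ref$steps_total)
    expect_equal(pick$mvpa_minutes[i], ref$mvpa_minutes)
    expect_equal(pick$morning_fraction[i], ref$morning_fraction)
  }
})

test_that("participant summaries average complete days and scale to weeks", {
  f <- tibble::tibble(
    participant_id = c(rep("A", 3), rep("B", 2)),
    day_index = c(1, 2, 3, 1, 2), weekday = c(0, 1, 2, 0, 1),
    date = as.Date("2016-01-11") + c(0, 1, 2, 0, 1),
    steps_total = c(8000, 8000, 8000, 6000, 7000),
    morning_fraction = 0.3, active_minutes = 100,
    mvpa_minutes = c(16, 16, 16, 10, 20), vigorous_minutes = 0,
    mvpa_steps = 1800
  )
  s <- participant_summary(f)
  expect_equal(s$mvpa_min_week[s$participant_id == "A"], 112) # 16 * 7
  expect_equal(s$mvpa_min_day[s$participant_id == "B"], 15)
  expect_equal(s$mvpa_min_week[s$participant_id == "B"], 105)
  expect_error(participant_summary(f[0, ]), "no complete days")
})

test_that("calendar-week aggregation agrees with daily-mean x 7 on balanced data", {
  f <- tibble::tibble(
    participant_id = "A", day_index = 1:14, weekday = (0:13) %% 7,
    date = as.Date("2016-01-11") + 0:13,
    steps_total = 7000, morning_fraction = 0.3, active_minutes = 100,
    mvpa_minutes = rep(c(10, 20), 7), vigorous_minutes = 0, mvpa_steps = 1500
  )
  a <- participant_summary(f, weekly = "daily_mean_x7")
  b <- participant_summary(f, weekly = "calendar_week")
  expect_equal(a$mvpa_min_week, b$mvpa_min_week)
})

test_that("recommendation thresholds are inclusive and nested", {
  s <- tibble::tibble(
    participant_id = c("A", "B", "C"),
    n_days = 60, steps_day = c(9999, 10000, 12000),
    active_min_day = 100, mvpa_min_day = c(150 / 7, 10, 30),
    vigorous_min_day = c(0, 0, 75 / 7), morning_fraction = 0.3,
    mvpa_min_week = c(150, 70, 210), vigorous_min_week = c(0, 0, 75)
  )
  w <- who_status(s)
  expect_true(w$who_mvpa_met[1])     # exactly 150 counts
  expect_false(w$steps10k_met[1])    # 9,999 misses
  expect_true(w$steps7k_met[1])
  expect_true(w$steps10k_met[2])     # exactly 10,000 counts
  expect_true(w$who_vigorous_met[3]) # exactly 75 vigorous counts
  expect_true(all(!w$steps10k_met | w$steps7k_met)) # 10k implies 7k
})

test_that("raising cadence never unmeets a recommendation (monotonicity)", {
  co <- generate_cohort(cohort_spec(n_participants = 6, seed = 31))
  asm <- assemble_days(co$steps, co$covariates)
  f <- daily_features(asm)
  base <- who_status(participant_summary(f))
  boosted <- f
  boosted$mvpa_minutes <- boosted$mvpa_minutes + 5
  boosted$vigorous_minutes <- boosted$vigorous_minutes + 5
  boosted$active_minutes <- boosted$active_minutes + 5
  boosted$steps_total <- boosted$steps_total + 1000L
  up <- who_status(participant_summary(boosted))
  for (col in c("who_mvpa_met", "who_vigorous_met", "steps10k_met", "steps7k_met")) {
    expect_true(all(up[[col]] >= base[[col]]))
  }
})

test_that("adherence counts worn days, not only full days", {
  cov <- make_covariates(c("P1", "P2"))
  s <- dplyr::bind_rows(
    full_day_records("P1", as.Date("2016-01-11") + 0:89),      # all 90 worn
    make_steps("P2", rep(as.character(as.Date("2016-01-11") + 0:44)), # 45 short days
               rep(600, 45), rep(30, 45))
  )
  a <- adherence_summary(assemble_days(s, cov))
  per <- attr(a, "by_participant")
  expect_equal(per$n_days_worn[per$participant_id == "P1"], 90L)
  expect_equal(per$n_days_worn[per$participant_id == "P2"], 45L)
  expect_equal(a$mean_pct_days_worn, mean(c(100, 50)))
  expect_equal(a$frac_worn_80plus, 0.5)
  # P2's last record is day 45: not wearing at the end
  expect_equal(a$frac_wearing_at_end, 0.5)
})

test_that("mean wearing fraction tracks the binomial expectation", {
  sp <- cohort_spec(n_participants = 80, seed = 32, missing_day_prob = 0.1,
                    missing_day_dispersion = 0) # homogeneous
  co <- generate_cohort(sp, resolution = "day")
  worn <- tapply(co$daily$status != "missing", co$daily$participant_id, mean)
  se <- sqrt(0.1 * 0.9 / (80 * 90))
  expect_lt(abs(mean(worn) - 0.9), 3 * se)
})
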