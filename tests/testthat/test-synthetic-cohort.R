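test_that("an empty specification yields an empty cohort and ground truth", {
  co <- generate_cohort(cohort_spec(n_participants = 0, seed = 1))
  expect_equal(nrow(co$steps), 0)
  expect_equal(nrow(co$ground_truth), 0)
  expect_equal(nrow(co$covariates), 0)
})

test_that("missing_day_prob = 1 leaves no records and no analyzable participant", {
  co <- generate_cohort(cohort_spec(n_participants = 4, missing_day_prob = 1,
                                    seed = 2))
  expect_equal(nrow(co$steps), 0)
  asm <- assemble_days(co$steps, co$covariates)
  expect_true(all(asm$participants$n_complete_days == 0))
  flt <- filter_adherent(asm)
  expect_equal(flt$summary$analyzable, 0)
  expect_equal(flt$summary$excluded, 4)
})

test_that("generation is bit-identical for a fixed seed", {
  sp <- cohort_spec(n_participants = 6, seed = 99)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a$steps, b$steps)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$ground_truth, b$ground_truth)
  d1 <- generate_cohort(sp, resolution = "day")
  d2 <- generate_cohort(sp, resolution = "day")
  expect_identical(d1$daily, d2$daily)
})

test_that("every participant appears exactly once in the ground truth", {
  co <- generate_cohort(cohort_spec(n_participants = 25, seed = 3),
                        resolution = "day")
  expect_equal(sort(co$ground_truth$participant_id),
               sort(co$covariates$participant_id))
  expect_equal(anyDuplicated(co$ground_truth$participant_id), 0L)
})

test_that("windows start on the Monday strictly after activation", {
  co <- generate_cohort(cohort_spec(n_participants = 10, seed = 4),
                        resolution = "day")
  starts <- tapply(co$windows$date, co$windows$participant_id, min)
  expect_true(all(format(as.Date(starts, origin = "1970-01-01"), "%u") == "1"))
  act <- co$covariates$activation_date[match(names(starts),
                                             co$covariates$participant_id)]
  gap <- as.integer(as.Date(starts, origin = "1970-01-01") - act)
  expect_true(all(gap >= 1 & gap <= 7))
})

test_that("minute streams contain only valid non-negative counts, one per minute", {
  co <- generate_cohort(cohort_spec(n_participants = 5, seed = 5))
  expect_true(all(co$steps$steps >= 1))
  expect_true(all(co$steps$steps == floor(co$steps$steps)))
  key <- paste(co$steps$participant_id, co$steps$timestamp)
  expect_equal(anyDuplicated(key), 0L)
})

test_that("partial days span less than 8 hours, full days at least 8", {
  co <- generate_cohort(cohort_spec(n_participants = 12, seed = 6,
                                    partial_day_prob = 0.3))
  asm <- assemble_days(co$steps, co$covariates)
  span <- asm$days$span_minutes[asm$days$any_record]
  full <- asm$days$full_day[asm$days$any_record]
  expect_true(all(span[full] >= 480))
  expect_true(all(span[!full] < 480))
  expect_gt(sum(!full), 0)
})

test_that("Sunday activity is depressed whenever sunday_multiplier < 1", {
  co <- generate_cohort(cohort_spec(n_participants = 100, seed = 7,
                                    sunday_multiplier = 0.75),
                        resolution = "day")
  d <- day_features(co)
  expect_lt(mean(d$steps_total[d$weekday == 6]),
            mean(d$steps_total[d$weekday < 6]))
  expect_lt(mean(d$mvpa_minutes[d$weekday == 6]),
            mean(d$mvpa_minutes[d$weekday < 6]))
})

test_that("per-class mean MVPA converges to the class means (n = 300)", {
  sp <- cohort_spec(n_participants = 300, seed = 8)
  co <- generate_cohort(sp, resolution = "day")
  d <- day_features(co)
  per <- tapply(d$mvpa_minutes, d$participant_id, mean)
  cls <- co$ground_truth$class[match(names(per), co$ground_truth$participant_id)]
  got <- tapply(per, cls, mean)[c("low", "moderate", "high")]
  expect_equal(as.vector(got), unname(sp$class_mvpa_means), tolerance = 0.10)
})

test_that("day-failure fraction matches its expectation within 3 standard errors", {
  sp <- cohort_spec(n_participants = 150, seed = 9)
  co <- generate_cohort(sp, resolution = "day")
  # a day fails the full-day rule when missing or partial
  p_hat <- mean(!co$daily$full_day)
  m <- sp$missing_day_prob
  p_exp <- m + (1 - m) * sp$partial_day_prob
  se <- sqrt(p_exp * (1 - p_exp) / nrow(co$daily)) +
    sd(tapply(!co$daily$full_day, co$daily$participant_id, mean)) /
      sqrt(sp$n_participants) # participant-level Beta heterogeneity
  expect_lt(abs(p_hat - p_exp), 3 * se)
})

test_that("day and minute resolutions share the day-level draws at a fixed seed", {
  sp <- cohort_spec(n_participants = 8, seed = 10)
  dm <- generate_cohort(sp, resolution = "day")
  mm <- generate_cohort(sp, resolution = "minute")
  asm <- assemble_days(mm$steps, mm$covariates)
  f_min <- daily_features(asm)
  f_day <- day_features(dm)
  key <- function(df) paste(df$participant_id, df$day_index)
  common <- intersect(key(f_min), key(f_day))
  expect_gt(length(common), 400)
  a <- f_min[match(common, key(f_min)), ]
  b <- f_day[match(common, key(f_day)), ]
  # identical day-level minute counts; step totals agree in distribution only
  expect_equal(a$mvpa_minutes, b$mvpa_minutes)
  expect_equal(a$active_minutes, b$active_minutes)
  expect_equal(mean(a$steps_total) / mean(b$steps_total), 1, tolerance = 0.02)
  expect_identical(dm$ground_truth, mm$ground_truth)
})

test_that("BMI class effect preserves marginal class proportions", {
  sp <- cohort_spec(n_participants = 400, seed = 11, bmi_class_effect = 0.2)
  co <- generate_cohort(sp, resolution = "day")
  props <- table(factor(co$ground_truth$class, c("low", "moderate", "high"))) / 400
  expect_equal(unname(as.vector(props)), unname(sp$class_proportions),
               tolerance = 0.25) # multinomial noise at n = 400, sd ~ 2.5pp
  # and higher BMI must shift membership towards the low class
  bmi_by_class <- tapply(co$covariates$bmi, co$ground_truth$class, mean)
  expect_gt(bmi_by_class[["low"]], bmi_by_class[["high"]])
})

test_that("written cohorts round-trip exactly", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_spec(n_participants = 2, seed = 12))
  write_cohort(co, dir)
  expect_length(list.files(file.path(dir, "streams")), 2)
  expect_true(file.exists(file.path(dir, "covariates.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))

  back <- read_cohort(dir)
  orig <- dplyr::arrange(co$steps, participant_id, timestamp)
  got <- dplyr::arrange(back$steps, participant_id, timestamp)
  expect_equal(got$participant_id, orig$participant_id)
  expect_identical(got$steps, orig$steps)
  expect_equal(got$timestamp, orig$timestamp)
  expect_equal(back$covariates$bmi, co$covariates$bmi)
  expect_equal(back$covariates$activation_date, co$covariates$activation_date)
})

test_that("an empty cohort writes a header-only covariate table", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_spec(n_participants = 0, seed = 13))
  write_cohort(co, dir)
  expect_length(list.files(file.path(dir, "streams")), 0)
  lines <- readLines(file.path(dir, "covariates.csv"))
  expect_length(lines, 1)
  expect_match(lines[1], "participant_id")
})
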