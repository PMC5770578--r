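test_that("read_step_stream parses, sorts and validates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,steps",
               "2016-01-11T08:01:00,30",
               "2016-01-11T08:00:00,12",
               "2016-01-11T09:30:00,105"), f)
  s <- read_step_stream(f, "P1")
  expect_equal(nrow(s), 3)
  expect_equal(s$steps, c(12L, 30L, 105L)) # sorted by time
  expect_s3_class(s, "step_stream")
})

test_that("a duplicate minute is rejected naming the minute", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,steps",
               "2016-01-11T08:00:00,30",
               "2016-01-11T08:00:30,12"), f) # same minute, different second
  expect_error(read_step_stream(f, "P1"), "duplicate.*08:00")
})

test_that("an empty data file yields a zero-record stream", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("timestamp,steps", f)
  expect_equal(nrow(read_step_stream(f)), 0)
})

test_that("negative and malformed rows are rejected with context", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,steps", "2016-01-11T08:00:00,-3"), f)
  expect_error(read_step_stream(f, "P1"), "negative")

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,steps", "2016-01-11T08:00:00,12",
               "not-a-time,5"), g)
  expect_error(read_step_stream(g, "P1"), "line 3|unparseable")
})

test_that("the observation window starts the first Monday strictly after activation", {
  w <- build_window(as.Date("2016-01-06")) # Wednesday
  expect_equal(w$date[1], as.Date("2016-01-11"))
  w <- build_window(as.Date("2016-01-04")) # Monday: strictly following
  expect_equal(w$date[1], as.Date("2016-01-11"))
  w <- build_window(as.Date("2016-01-10")) # Sunday
  expect_equal(w$date[1], as.Date("2016-01-11"))
  # calendar oracle: 90 consecutive days end start + 89
  expect_equal(w$date[90], as.Date("2016-01-11") + 89)
  expect_equal(w$date[90], as.Date("2016-04-09"))
  expect_equal(nrow(w), 90)
  expect_equal(w$weekday, (0:89) %% 7)
})

test_that("the full-day rule needs >= 8 h between first and last steps", {
  expect_true(is_full_day(make_day(c(8 * 60, 1, 50), c(20 * 60, 1, 50))))   # 720 min
  expect_false(is_full_day(make_day(c(10 * 60, 1, 50), c(14 * 60, 1, 50)))) # 240 min
  expect_false(is_full_day(make_day(c(9 * 60, 1, 50))))                     # span 0
  expect_false(is_full_day(integer(1440)))                                  # no steps
  # exact boundary is inclusive
  expect_true(is_full_day(make_day(c(600, 1, 5), c(1080, 1, 5))))
})

test_that("full-day status is monotone under added earlier/later records", {
  day <- make_day(c(10 * 60, 1, 40), c(19 * 60, 1, 40))
  expect_true(is_full_day(day))
  for (extra in c(5 * 60, 23 * 60)) {
    wider <- day
    wider[extra + 1L] <- 10L
    expect_true(is_full_day(wider))
  }
})

test_that("records outside the window are discarded and counted", {
  cov <- make_covariates("P1", activation = as.Date("2016-01-06"))
  # one record well before the window, two full in-window days
  s <- dplyr::bind_rows(
    make_steps("P1", "2015-12-01", 600, 40),
    full_day_records("P1", as.Date("2016-01-11") + 0:1)
  )
  asm <- assemble_days(s, cov)
  expect_equal(asm$participants$out_of_window_records, 1L)
  expect_equal(asm$participants$n_complete_days, 2L)
  expect_equal(nrow(asm$days), 90)
})

test_that("a stream entirely before the window yields zero complete days", {
  cov <- make_covariates("P1")
  s <- make_steps("P1", "2015-06-01", c(480, 1200), c(50, 60))
  asm <- assemble_days(s, cov)
  expect_equal(asm$participants$n_complete_days, 0L)
  expect_equal(asm$participants$n_days_worn, 0L)
})

test_that("90 wide days give 90 complete days", {
  cov <- make_covariates("P1")
  s <- full_day_records("P1", as.Date("2016-01-11") + 0:89)
  asm <- assemble_days(s, cov)
  expect_equal(asm$participants$n_complete_days, 90L)
})

test_that("steps are conserved from stream to day profiles", {
  co <- generate_cohort(cohort_spec(n_participants = 5, seed = 20))
  asm <- assemble_days(co$steps, co$covariates)
  by_stream <- tapply(co$steps$steps, co$steps$participant_id, sum)
  by_days <- tapply(asm$days$steps_total, asm$days$participant_id, sum)
  ids <- names(by_stream)
  expect_true(all(asm$participants$out_of_window_records == 0)) # generated in-window
  expect_equal(as.vector(by_days[ids]), as.vector(by_stream[ids]))
  # and the 1440-slot day profile agrees with the day table
  d1 <- day_profile(asm, ids[1], 3)
  expect_equal(sum(d1), asm$days$steps_total[asm$days$participant_id == ids[1] &
                                               asm$days$day_index == 3])
  expect_length(d1, 1440)
})

test_that("the adherence filter is boundary-inclusive at 60 complete days", {
  cov <- make_covariates(c("P1", "P2"))
  s <- dplyr::bind_rows(
    full_day_records("P1", as.Date("2016-01-11") + 0:59), # 60 complete
    full_day_records("P2", as.Date("2016-01-11") + 0:58)  # 59 complete
  )
  flt <- filter_adherent(assemble_days(s, cov))
  expect_equal(flt$analyzable$participants$participant_id, "P1")
  expect_equal(flt$excluded$participants$participant_id, "P2")
  expect_equal(flt$summary$included, 2L)
  expect_equal(flt$summary$analyzable + flt$summary$excluded, flt$summary$included)
})

test_that("assemble -> write -> read -> assemble is idempotent", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_spec(n_participants = 3, seed = 21))
  asm1 <- assemble_days(co$steps, co$covariates)
  write_cohort(co, dir)
  back <- read_cohort(dir)
  asm2 <- assemble_days(back$steps, back$covariates)
  expect_equal(asm2$days$steps_total, asm1$days$steps_total)
  expect_equal(asm2$days$full_day, asm1$days$full_day)
  expect_equal(asm2$participants$n_complete_days, asm1$participants$n_complete_days)
})
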