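#' Generate a synthetic tracker cohort with known ground truth
#'
#' Simulates minute-level step streams (or, with `resolution = "day"`, their
#' daily aggregates) for a cohort of participants wearing a step tracker
#' over a 90-day observation window starting the first Monday after device
#' activation. Each participant belongs to one of three latent MVPA classes
#' (low / moderate / high) whose mean activity is constant over time;
#' Sundays are quieter by a multiplicative factor; days can be fully missing
#' (non-wear) or partial (records confined to a short < 8 h span, failing
#' the full-day rule); a higher BMI multiplicatively lowers activity.
#'
#' The day-level model is drawn first (classes, covariates, per-day statuses
#' and minute counts by cadence band), then — only at minute resolution —
#' each active minute is placed into a clock slot following a fixed diurnal
#' profile and given a cadence from its band's distribution. Both
#' resolutions therefore share the day-level draws: for a fixed seed, daily
#' MVPA and active-minute counts and day statuses are identical across
#' resolutions, while daily step totals agree in distribution (day mode
#' draws band step sums directly).
#'
#' @param spec A [cohort_spec()].
#' @param resolution `"minute"` (full streams, the primary product) or
#'   `"day"` (daily aggregates only; much faster, used for replicated
#'   simulations).
#' @return An object of class `step_cohort`: a list with elements
#'   `steps` (minute records: `participant_id`, `timestamp`, `steps`;
#'   minute resolution only), `daily` (day-level table; day resolution
#'   only), `covariates`, `ground_truth`, `windows`, `spec`, `resolution`.
#'   Ground truth (latent class and generating means) is kept separate from
#'   the covariate table so downstream stages cannot consume labels.
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n_participants = 4, seed = 7))
#' head(co$steps)
#' co$ground_truth
generate_cohort <- function(spec, resolution = c("minute", "day")) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  resolution <- match.arg(resolution)
  set.seed(spec$seed)

  n <- spec$n_participants
  if (n == 0) {
    return(empty_cohort(spec, resolution))
  }

  ids <- sprintf("P%04d", seq_len(n))
  cm <- spec$covariate_model

  ## --- participants: disease group, covariates, latent class ------------
  grp <- sample(rep(c("RA", "axSpA"), largest_remainder(n, c(cm$prop_ra, 1 - cm$prop_ra))))
  gpar <- function(field) {
    vapply(grp, function(g) cm[[g]][[field]], numeric(1), USE.NAMES = FALSE)
  }
  sex <- ifelse(runif(n) < gpar("female_p"), "female", "male")
  age <- rtnorm(n, gpar("age_mean"), gpar("age_sd"), 18, 90)
  bmi <- rtnorm(n, gpar("bmi_mean"), gpar("bmi_sd"), 16, 50)
  duration <- rgamma_ms(n, gpar("duration_mean"), gpar("duration_sd"))
  biologic <- runif(n) < gpar("biologic_p")
  employed <- runif(n) < gpar("employed_p")
  ptga <- rtnorm(n, gpar("ptga_mean"), gpar("ptga_sd"), 0, 10)
  score <- rtnorm(n, gpar("score_mean"), gpar("score_sd"), 0, 10)
  activation <- spec$activation_range[1] +
    sample.int(as.integer(diff(spec$activation_range)) + 1L, n, replace = TRUE) - 1L

  klass <- draw_classes(bmi, spec$class_proportions, spec$bmi_class_effect)
  ki <- match(klass, c("low", "moderate", "high"))
  bmi_mult <- exp(spec$bmi_effect_log * (bmi - 25))
  mvpa_mean <- rgamma_ms(n, spec$class_mvpa_means[ki], spec$class_mvpa_sds[ki])
  steps_base <- rgamma_ms(n, spec$class_daily_steps_means[ki], spec$class_daily_steps_sd) +
    ifelse(grp == "axSpA", spec$group_effect_steps, 0)
  steps_mean <- pmax(steps_base, 300) * bmi_mult
  miss_p <- rbeta_mean(n, spec$missing_day_prob, spec$missing_day_dispersion)

  covariates <- tibble::tibble(
    participant_id = ids, disease_group = grp, sex = sex,
    age = round(age, 1), bmi = round(bmi, 1),
    disease_duration = round(duration, 1),
    biologic = biologic, employed = employed, ptga = round(ptga, 1),
    das28 = ifelse(grp == "RA", round(score, 1), NA_real_),
    basdai = ifelse(grp == "axSpA", round(score, 1), NA_real_),
    activation_date = activation
  )
  ground_truth <- tibble::tibble(
    participant_id = ids, class = klass,
    mvpa_mean = mvpa_mean, steps_mean = steps_mean,
    bmi_multiplier = bmi_mult, missing_day_prob = miss_p
  )
  windows <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    w <- build_window(activation[i])
    w$participant_id <- ids[i]
    w
  }))[, c("participant_id", "day_index", "date", "weekday")]

  ## --- day-level draws ---------------------------------------------------
  nd <- n * 90L
  pd <- tibble::tibble(
    row = seq_len(nd),
    pid = rep(seq_len(n), each = 90L),
    participant_id = rep(ids, each = 90L),
    day_index = rep(1:90, n)
  )
  pd$weekday <- (pd$day_index - 1L) %% 7L # windows start Monday: 0 = Mon .. 6 = Sun
  # Sunday dip, normalized so the mean multiplier over a week is exactly 1:
  # class means then remain week-average activity levels
  wk_norm <- 7 / (6 + spec$sunday_multiplier)
  day_mult <- ifelse(pd$weekday == 6L, spec$sunday_multiplier, 1) * wk_norm

  u_miss <- runif(nd)
  u_part <- runif(nd)
  status <- ifelse(u_miss < miss_p[pd$pid], "missing",
                   ifelse(u_part < spec$partial_day_prob, "partial", "full"))
  window_hours <- ifelse(status == "partial", sample(1:7, nd, replace = TRUE), 16L)
  scale_f <- ifelse(status == "missing", 0, window_hours / 16)

  cmod <- cadence_model()
  s_target <- rgamma_cv(nd, steps_mean[pd$pid] * day_mult, spec$steps_day_cv) * scale_f
  m_min <- round(rgamma_cv(nd, mvpa_mean[pd$pid] * day_mult, spec$mvpa_day_cv) * scale_f)
  nonmvpa_steps <- pmax(0, s_target - cmod$mvpa_mean * m_min)
  a_min <- round(nonmvpa_steps * 0.78 / cmod$act_mean)
  l_min <- round(nonmvpa_steps * 0.22 / cmod$light_mean)
  m_min[status == "missing"] <- 0L
  a_min[status == "missing"] <- 0L
  l_min[status == "missing"] <- 0L

  # clamp to the day's clock capacity (17 weighted hours on a full day, the
  # drawn window on a partial day) so minute placement can never overflow
  capacity <- ifelse(status == "partial", window_hours * 60L,
                     sum(cmod$hour_w > 0) * 60L)
  total <- m_min + a_min + l_min
  over <- total > capacity
  if (any(over)) {
    sc <- capacity[over] / total[over]
    m_min[over] <- floor(m_min[over] * sc)
    a_min[over] <- floor(a_min[over] * sc)
    l_min[over] <- floor(l_min[over] * sc)
  }

  pd$status <- status
  pd$window_hours <- window_hours
  pd$mvpa_minutes <- as.integer(m_min)
  pd$nonmvpa_active_minutes <- as.integer(a_min)
  pd$light_minutes <- as.integer(l_min)

  pd <- dplyr::left_join(pd, windows, by = c("participant_id", "day_index", "weekday"))

  out <- list(
    resolution = resolution, covariates = covariates,
    ground_truth = ground_truth, windows = windows, spec = spec
  )
  if (resolution == "day") {
    out$daily <- realize_daily(pd, cmod)
  } else {
    out$steps <- realize_minutes(pd, cmod)
  }
  structure(out, class = "step_cohort")
}

empty_cohort <- function(spec, resolution) {
  out <- list(
    resolution = resolution,
    covariates = tibble::tibble(
      participant_id = character(), disease_group = character(),
      sex = character(), age = numeric(), bmi = numeric(),
      disease_duration = numeric(), biologic = logical(),
      employed = logical(), ptga = numeric(), das28 = numeric(),
      basdai = numeric(), activation_date = as.Date(character())
    ),
    ground_truth = tibble::tibble(
      participant_id = character(), class = character(),
      mvpa_mean = numeric(), steps_mean = numeric(),
      bmi_multiplier = numeric(), missing_day_prob = numeric()
    ),
    windows = tibble::tibble(
      participant_id = character(), day_index = integer(),
      date = as.Date(character()), weekday = integer()
    ),
    spec = spec
  )
  if (resolution == "day") {
    out$daily <- tibble::tibble(
      participant_id = character(), day_index = integer(),
      date = as.Date(character()), weekday = integer(), status = character(),
      full_day = logical(), steps_total = integer(), active_minutes = integer(),
      mvpa_minutes = integer(), vigorous_minutes = integer(),
      mvpa_steps = integer(), morning_fraction = numeric()
    )
  } else {
    out$steps <- tibble::tibble(
      participant_id = character(),
      timestamp = as.POSIXct(character(), tz = "UTC"), steps = integer()
    )
  }
  structure(out, class = "step_cohort")
}

## Cadence distributions of the three minute bands (all integer steps/min):
##  - MVPA minutes:    100 + floor(Gamma(shape 2, scale 10))        (>= 100)
##  - active minutes:  20 + min(floor(Gamma(shape 1.6, scale 16)), 79) (20..99)
##  - light minutes:   1..19 with geometrically decaying weights    (1..19)
## Exact moments are derived from the discretized distributions so that the
## day-resolution aggregate draws match the minute-resolution sums.
cadence_model <- function() {
  j <- 0:199
  p_mvpa <- pgamma(j + 1, 2, scale = 10) - pgamma(j, 2, scale = 10)
  p_mvpa[200] <- p_mvpa[200] + pgamma(200, 2, scale = 10, lower.tail = FALSE)
  mvpa_mean <- 100 + sum(j * p_mvpa)
  p_vig <- sum(p_mvpa[j >= 30]) # cadence >= 130

  k <- 0:79
  p_act <- pgamma(k + 1, 1.6, scale = 16) - pgamma(k, 1.6, scale = 16)
  p_act[80] <- p_act[80] + pgamma(80, 1.6, scale = 16, lower.tail = FALSE)
  act_mean <- 20 + sum(k * p_act)
  act_var <- sum((20 + k)^2 * p_act) - act_mean^2

  lv <- 1:19
  lw <- exp(-(lv - 1) / 8)
  lw <- lw / sum(lw)
  light_mean <- sum(lv * lw)
  light_var <- sum(lv^2 * lw) - light_mean^2

  hour_w <- c(rep(0, 6), 0.2, 1.0, 1.2, 0.9, 0.7, 0.7,
              1.0, 0.9, 0.7, 0.7, 0.8, 1.1, 1.3, 1.2, 0.8, 0.5, 0.3, 0)

  list(mvpa_mean = mvpa_mean, p_vig = p_vig,
       act_mean = act_mean, act_var = act_var, act_p = p_act,
       light_mean = light_mean, light_var = light_var, light_w = lw,
       hour_w = hour_w)
}

## Day-resolution realization: band step sums drawn directly.
## The MVPA band sum uses the exact Gamma-sum representation; the active and
## light band sums use a normal approximation to the sum of m iid discrete
## cadences (central limit theorem; m is typically 60-150).
realize_daily <- function(pd, cmod) {
  nd <- nrow(pd)
  m <- pd$mvpa_minutes; a <- pd$nonmvpa_active_minutes; l <- pd$light_minutes
  vig <- rbinom(nd, m, cmod$p_vig)
  mvpa_steps <- ifelse(m > 0, 100 * m + round(rgamma(nd, shape = 2 * m, scale = 10)), 0)
  act_steps <- ifelse(a > 0,
                      pmin(pmax(round(rnorm(nd, a * cmod$act_mean, sqrt(a * cmod$act_var))),
                                a * 20), a * 99), 0)
  light_steps <- ifelse(l > 0,
                        pmin(pmax(round(rnorm(nd, l * cmod$light_mean,
                                              sqrt(l * cmod$light_var))),
                                  l * 1), l * 19), 0)
  morning <- rbeta(nd, 0.336 * 40, (1 - 0.336) * 40)
  steps_total <- mvpa_steps + act_steps + light_steps

  tibble::tibble(
    participant_id = pd$participant_id, day_index = pd$day_index,
    date = pd$date, weekday = pd$weekday, status = pd$status,
    full_day = pd$status == "full",
    steps_total = ifelse(pd$status == "missing", NA_integer_, as.integer(steps_total)),
    active_minutes = ifelse(pd$status == "missing", NA_integer_, as.integer(m + a)),
    mvpa_minutes = ifelse(pd$status == "missing", NA_integer_, as.integer(m)),
    vigorous_minutes = ifelse(pd$status == "missing", NA_integer_, as.integer(vig)),
    mvpa_steps = ifelse(pd$status == "missing", NA_integer_, as.integer(mvpa_steps)),
    morning_fraction = ifelse(pd$status == "missing" | steps_total == 0,
                              NA_real_, morning)
  )
}

## Minute-resolution realization: place each minute into a clock slot.
## Hours are drawn from the diurnal profile (multinomial per day), distinct
## minutes within each hour; band labels are randomly interleaved so every
## band follows the same diurnal shape.
realize_minutes <- function(pd, cmod) {
  act <- pd[pd$status != "missing", , drop = FALSE]
  ntot <- act$mvpa_minutes + act$nonmvpa_active_minutes + act$light_minutes
  act <- act[ntot > 0, , drop = FALSE]
  ntot <- ntot[ntot > 0]
  if (nrow(act) == 0) {
    return(tibble::tibble(participant_id = character(),
                          timestamp = as.POSIXct(character(), tz = "UTC"),
                          steps = integer()))
  }

  nrows <- nrow(act)
  slot_list <- vector("list", nrows)
  start_hour <- ifelse(act$status == "partial",
                       sample(9:14, nrows, replace = TRUE), 0L)
  for (i in seq_len(nrows)) {
    if (act$status[i] == "partial") {
      hrs <- start_hour[i] + seq_len(act$window_hours[i]) - 1L
      w <- cmod$hour_w[hrs + 1L]
      if (sum(w) <= 0) w <- rep(1, length(hrs))
    } else {
      hrs <- 0:23
      w <- cmod$hour_w
    }
    hc <- as.vector(rmultinom(1, ntot[i], w))
    over <- hc > 60L
    while (any(over)) { # capacity overflow: push excess into free hours
      excess <- sum(hc[over] - 60L)
      hc[over] <- 60L
      free <- which(hc < 60L & w > 0)
      if (length(free) == 0) free <- which(hc < 60L)
      add <- as.vector(rmultinom(1, excess, pmax(w[free], 1e-9)))
      hc[free] <- hc[free] + add
      over <- hc > 60L
    }
    mins <- unlist(lapply(which(hc > 0L), function(h) {
      (hrs[h] * 60L) + sample.int(60L, hc[h]) - 1L
    }), use.names = FALSE)
    slot_list[[i]] <- mins
  }

  minute_of_day <- unlist(slot_list, use.names = FALSE)
  day_row <- rep(seq_len(nrows), ntot)

  # random interleaving of bands within each day
  band <- unlist(lapply(seq_len(nrows), function(i) {
    b <- rep.int(c(3L, 2L, 1L),
                 c(act$mvpa_minutes[i], act$nonmvpa_active_minutes[i],
                   act$light_minutes[i]))
    if (length(b) > 1) b[sample.int(length(b))] else b
  }), use.names = FALSE)

  steps <- integer(length(band))
  is_m <- band == 3L; is_a <- band == 2L; is_l <- band == 1L
  steps[is_m] <- 100L + pmin(as.integer(floor(rgamma(sum(is_m), 2, scale = 10))), 199L)
  steps[is_a] <- 20L + pmin(as.integer(floor(rgamma(sum(is_a), 1.6, scale = 16))), 79L)
  steps[is_l] <- sample(1:19, sum(is_l), replace = TRUE, prob = cmod$light_w)

  out <- tibble::tibble(
    participant_id = act$participant_id[day_row],
    timestamp = as.POSIXct(act$date[day_row], tz = "UTC") + minute_of_day * 60,
    steps = steps
  )
  dplyr::arrange(out, .data$participant_id, .data$timestamp)
}

## -- small sampling helpers ----------------------------------------------

# gamma parameterized by mean and sd (mean 0 -> 0)
rgamma_ms <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- numeric(n)
  ok <- mean > 0 & sd > 0
  if (any(ok)) {
    shape <- (mean[ok] / sd[ok])^2
    out[ok] <- rgamma(sum(ok), shape = shape, rate = shape / mean[ok])
  }
  out[mean > 0 & sd <= 0] <- mean[mean > 0 & sd <= 0]
  out
}

# gamma parameterized by mean and coefficient of variation
rgamma_cv <- function(n, mean, cv) {
  mean <- rep_len(mean, n)
  if (cv <= 0) return(mean)
  shape <- 1 / cv^2
  out <- numeric(n)
  ok <- mean > 0
  out[ok] <- rgamma(sum(ok), shape = shape, rate = shape / mean[ok])
  out
}

# truncated normal through the probability-integral transform
rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  stats::qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

# beta parameterized by mean and concentration (a + b); degenerate ends kept
rbeta_mean <- function(n, mean, size) {
  if (mean <= 0) return(rep(0, n))
  if (mean >= 1) return(rep(1, n))
  if (size <= 0) return(rep(mean, n))
  rbeta(n, mean * size, (1 - mean) * size)
}

## Latent activity-class assignment. With gamma = 0, class counts are exact
## (largest-remainder, shuffled). With gamma > 0, membership follows an
## ordered logit on centred BMI whose intercepts are calibrated against the
## realized BMI vector so the marginal class proportions match the target
## whatever the effect size (higher BMI -> lower activity class).
draw_classes <- function(bmi, proportions, gamma) {
  labels <- c("low", "moderate", "high")
  if (gamma == 0) {
    return(sample(rep(labels, largest_remainder(length(bmi), proportions))))
  }
  b <- bmi - 25
  calib <- function(target) {
    stats::uniroot(function(a) mean(stats::plogis(a + gamma * b)) - target,
                   c(-50, 50), tol = 1e-10)$root
  }
  p <- proportions / sum(proportions)
  a1 <- calib(p[1])
  a2 <- calib(p[1] + p[2])
  p1 <- stats::plogis(a1 + gamma * b)
  p2 <- stats::plogis(a2 + gamma * b)
  u <- runif(length(bmi))
  labels[1L + (u > p1) + (u > p2)]
}

# integer counts with the stated proportions (largest-remainder rounding)
largest_remainder <- function(n, p) {
  p <- p / sum(p)
  cnt <- floor(n * p)
  rem <- n - sum(cnt)
  if (rem > 0) {
    frac <- n * p - cnt
    take <- order(frac, decreasing = TRUE)[seq_len(rem)]
    cnt[take] <- cnt[take] + 1
  }
  as.integer(cnt)
}

#' @export
print.step_cohort <- function(x, ...) {
  cat(sprintf("<step_cohort> %d participants, %s resolution\n",
              nrow(x$covariates), x$resolution))
  if (!is.null(x$steps)) {
    cat(sprintf("  %d minute records\n", nrow(x$steps)))
  }
  if (!is.null(x$daily)) {
    cat(sprintf("  %d participant-days (day-level)\n", nrow(x$daily)))
  }
  invisible(x)
}
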