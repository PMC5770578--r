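test_that("the design sample size reproduces the closed form", {
  expect_identical(sample_size_two_means(1500, 3300, 0.80, 0.05), 76L)
  # delta = sd: 2 * (1.96 + 0.8416)^2 = 15.70 -> 16
  expect_identical(sample_size_two_means(1, 1, 0.80, 0.05), 16L)
  # unbounded effect: floor at one participant per group
  expect_identical(sample_size_two_means(Inf, 3300), 1L)
  expect_error(sample_size_two_means(-5, 10), "delta")
  expect_error(sample_size_two_means(5, 0), "sd")
  expect_error(sample_size_two_means(5, 10, power = 1.2), "power")
})

test_that("sample size is monotone in effect, spread and power", {
  deltas <- c(500, 1000, 1500, 3000)
  n_d <- vapply(deltas, function(d) sample_size_two_means(d, 3300), integer(1))
  expect_true(all(diff(n_d) <= 0))
  sds <- c(1000, 2000, 3300, 5000)
  n_s <- vapply(sds, function(s) sample_size_two_means(1500, s), integer(1))
  expect_true(all(diff(n_s) >= 0))
  pws <- c(0.5, 0.8, 0.9, 0.99)
  n_p <- vapply(pws, function(p) sample_size_two_means(1500, 3300, power = p),
                integer(1))
  expect_true(all(diff(n_p) >= 0))
})

test_that("the t-based iteration agrees with power.t.test", {
  ours <- sample_size_two_means(1500, 3300, 0.80, 0.05, method = "t")
  ref <- ceiling(stats::power.t.test(delta = 1500, sd = 3300, power = 0.80,
                                     sig.level = 0.05)$n)
  expect_equal(ours, ref)
  ours2 <- sample_size_two_means(10, 12, 0.9, 0.05, method = "t")
  ref2 <- ceiling(stats::power.t.test(delta = 10, sd = 12, power = 0.9)$n)
  expect_equal(ours2, ref2)
})

lmm_day_data <- function(n = 24, seed = 50, offset = 0) {
  sp <- cohort_spec(n_participants = n, seed = seed, group_effect_steps = offset)
  co <- generate_cohort(sp, resolution = "day")
  dplyr::left_join(day_features(co), co$covariates, by = "participant_id")
}

test_that("groups with fewer than two participants are rejected", {
  dd <- lmm_day_data(n = 20, seed = 51)
  one_ax <- dd[dd$disease_group == "RA" |
                 dd$participant_id == dd$participant_id[dd$disease_group == "axSpA"][1], ]
  expect_error(fit_group_lmm(one_ax, "steps_total"), "at least 2 participants")
  ra_only <- dd[dd$disease_group == "RA", ]
  expect_error(fit_group_lmm(ra_only, "steps_total"), "2 disease groups")
})

test_that("with one observation per participant the fit collapses to least squares", {
  dd <- lmm_day_data(n = 30, seed = 52)
  one <- dd[!duplicated(dd$participant_id), ]
  fit <- fit_group_lmm(one, "steps_total", covariates = c("bmi", "age"),
                       var_power = "never", engine = "nlme",
                       random_slope = FALSE)
  ols <- lm(steps_total ~ disease_group + day_index + bmi + age, data = one)
  expect_equal(unname(fit$tidy$estimate), unname(coef(ols)), tolerance = 1e-6)
})

test_that("a large group offset is detected and signed correctly", {
  dd <- lmm_day_data(n = 60, seed = 53, offset = 3000)
  fit <- fit_group_lmm(dd, "steps_total", engine = "lmer")
  expect_true(fit$converged)
  expect_lt(fit$group_p, 0.01)
  expect_gt(fit$group_estimate, 0) # axSpA raised relative to RA baseline
  expect_equal(fit$n_obs, nrow(dd[complete.cases(dd[, c("steps_total")]), ]))
})

test_that("both engines agree on the group comparison", {
  dd <- lmm_day_data(n = 30, seed = 54)
  f1 <- fit_group_lmm(dd, "steps_total", var_power = "never", engine = "nlme")
  f2 <- fit_group_lmm(dd, "steps_total", engine = "lmer")
  # REML optima may differ slightly when the slope variance is near zero;
  # the group contrast must agree well within statistical resolution
  se <- f2$tidy$std.error[2]
  expect_lt(abs(f1$group_estimate - f2$group_estimate), 0.25 * se)
  # without random slopes the likelihoods are well-behaved: tight agreement
  g1 <- fit_group_lmm(dd, "steps_total", var_power = "never", engine = "nlme",
                      random_slope = FALSE)
  g2 <- fit_group_lmm(dd, "steps_total", engine = "lmer", random_slope = FALSE)
  expect_equal(g1$tidy$estimate, g2$tidy$estimate, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("a single-class outcome cannot be modelled", {
  cov <- make_covariates(paste0("P", 1:10))
  st <- tibble::tibble(participant_id = cov$participant_id,
                       who_mvpa_met = TRUE)
  expect_error(fit_who_logistic(st, cov), "single class")
})

test_that("collinear covariates raise the aliasing diagnostic", {
  cov <- make_covariates(paste0("P", 1:40))
  cov$group_copy <- cov$disease_group
  set.seed(55)
  st <- tibble::tibble(participant_id = cov$participant_id,
                       who_mvpa_met = runif(40) < 0.5)
  fit <- fit_who_logistic(st, cov,
                          terms = c("disease_group", "group_copy", "bmi"))
  expect_gt(length(fit$collinear), 0)
})

test_that("rescaled covariates obey the odds-ratio power law", {
  set.seed(56)
  n <- 300
  df <- tibble::tibble(
    participant_id = paste0("P", 1:n),
    bmi = rnorm(n, 25, 4),
    y = runif(n) < stats::plogis(-2 + 0.1 * (rnorm(n, 25, 4)))
  )
  df$y <- runif(n) < stats::plogis(-2.5 + 0.1 * df$bmi)
  f1 <- fit_logistic_core(df, "y", "bmi", rescale = list())      # per unit
  f5 <- fit_logistic_core(df, "y", "bmi", rescale = list(bmi = 5)) # per 5
  expect_equal(f5$tidy$or, f1$tidy$or^5, tolerance = 1e-10)
  expect_equal(f5$tidy$estimate, f1$tidy$estimate) # log-odds unchanged
})

test_that("the low-cluster regression reports BMI per 5 units with age dichotomized", {
  co <- generate_cohort(cohort_spec(n_participants = 120, seed = 57),
                        resolution = "day")
  f <- day_features(co)
  tm <- impute_missing_days(trajectory_matrix(f, participants = adherent_ids(co)))
  km <- kmeans_longitudinal(tm, 3, seed = 57)
  fit <- fit_low_cluster_logistic(km, co$covariates)
  expect_true("age_ge60TRUE" %in% fit$tidy$term)
  bmi_row <- fit$tidy[fit$tidy$term == "bmi", ]
  expect_equal(bmi_row$or_units, 5)
  expect_equal(bmi_row$or, exp(5 * bmi_row$estimate))
  expect_true(all(fit$tidy$ci_low <= fit$tidy$or & fit$tidy$or <= fit$tidy$ci_high))
  expect_true(all(fit$tidy$or > 0))
})

test_that("an empty or all-encompassing low cluster is rejected", {
  x <- matrix(rnorm(60), 6, 10)
  rownames(x) <- paste0("P", 1:6)
  km <- kmeans_longitudinal(x, k = 1, seed = 1)
  expect_error(fit_low_cluster_logistic(km, make_covariates(rownames(x))),
               "low-activity cluster")
})
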