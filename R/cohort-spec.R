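#' Specification of a synthetic tracker cohort
#'
#' Bundles every parameter of the synthetic-cohort generator: cohort size,
#' latent moderate-to-vigorous physical activity (MVPA) classes, day-to-day
#' variability, weekly periodicity, non-wear behaviour, and the covariate
#' model. The defaults emulate a published 90-day tracker cohort of patients
#' with rheumatoid arthritis (RA) and axial spondyloarthritis (axSpA): three
#' latent MVPA classes with constant-in-mean trajectories (7.2 / 23.8 / 49.4
#' min/day in proportions 54.1 / 42.7 / 3.2 %), a cohort mean of about 7124
#' steps/day, reduced Sunday activity, and intermittent fully-missing and
#' partial (short-span) days.
#'
#' @param n_participants Number of participants to generate.
#' @param class_proportions Named fractions (`low`, `moderate`, `high`)
#'   of the three latent MVPA classes; must sum to 1.
#' @param class_mvpa_means Mean MVPA minutes/day (cadence >= 100 steps/min)
#'   per class.
#' @param class_mvpa_sds Between-participant SD of mean MVPA minutes/day
#'   within each class.
#' @param class_daily_steps_means Mean steps/day per class. The defaults are
#'   chosen so the class-weighted mean is ~7124 steps/day.
#' @param class_daily_steps_sd Between-participant SD of mean steps/day
#'   within a class.
#' @param mvpa_day_cv,steps_day_cv Within-participant day-to-day coefficient
#'   of variation of daily MVPA minutes and daily steps.
#' @param sunday_multiplier Multiplier in (0, 1] applied to all activity
#'   means on Sundays (weekly periodicity; < 1 means quieter Sundays).
#' @param missing_day_prob Cohort-mean per-day probability that a day is
#'   fully missing (device not worn / not synced: no records at all).
#' @param missing_day_dispersion Concentration of the per-participant Beta
#'   distribution of the missing-day probability (larger = more
#'   between-participant heterogeneity is `1/(x+1)`-ish smaller; this is the
#'   Beta "sample size" `a + b`). Heterogeneous non-wear is what makes some
#'   participants fall below the 60-full-day adherence threshold.
#' @param partial_day_prob Per-day probability that a worn day is "partial":
#'   records are confined to a short (< 8 h) span, so the day fails the
#'   full-day rule.
#' @param bmi_effect_log Log-multiplier on a participant's mean daily steps
#'   per BMI unit above 25 kg/m2 (negative = heavier participants walk
#'   less). Acts multiplicatively so means stay non-negative.
#' @param bmi_class_effect Ordered-logit coefficient (per BMI unit) tilting
#'   latent-class membership towards lower activity with higher BMI. The
#'   logit intercepts are calibrated numerically against the cohort's
#'   realized BMI distribution so the marginal class proportions stay at
#'   `class_proportions` whatever the effect size; within-class activity
#'   draws remain BMI-independent. Set to 0 (together with
#'   `bmi_effect_log = 0`) for a BMI-null cohort.
#' @param group_effect_steps Additive shift (steps/day) applied to the
#'   axSpA group's mean daily steps; 0 by default (the two diseases have
#'   identical generated activity). Used for power simulations.
#' @param covariate_model Per-group covariate distributions; see
#'   [covariate_model_defaults()].
#' @param activation_range Character vector of two dates; each participant's
#'   device-activation date is drawn uniformly between them.
#' @param seed Integer seed; a fixed seed makes generation bit-identical.
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @seealso [generate_cohort()], [covariate_model_defaults()]
#' @export
#' @examples
#' spec <- cohort_spec(n_participants = 20, seed = 1)
#' spec$class_mvpa_means
cohort_spec <- function(n_participants = 157,
                        class_proportions = c(low = 0.541, moderate = 0.427, high = 0.032),
                        class_mvpa_means = c(low = 7.2, moderate = 23.8, high = 49.4),
                        class_mvpa_sds = c(low = 3.0, moderate = 4.5, high = 8.5),
                        class_daily_steps_means = c(low = 6000, moderate = 8310, high = 10300),
                        class_daily_steps_sd = 1900,
                        mvpa_day_cv = 0.5,
                        steps_day_cv = 0.3,
                        sunday_multiplier = 0.75,
                        missing_day_prob = 0.12,
                        missing_day_dispersion = 4,
                        partial_day_prob = 0.04,
                        bmi_effect_log = -0.01,
                        bmi_class_effect = 0.15,
                        group_effect_steps = 0,
                        covariate_model = covariate_model_defaults(),
                        activation_range = c("2016-01-04", "2016-04-29"),
                        seed = 20160104) {
  spec <- list(
    n_participants = n_participants,
    class_proportions = class_proportions,
    class_mvpa_means = class_mvpa_means,
    class_mvpa_sds = class_mvpa_sds,
    class_daily_steps_means = class_daily_steps_means,
    class_daily_steps_sd = class_daily_steps_sd,
    mvpa_day_cv = mvpa_day_cv,
    steps_day_cv = steps_day_cv,
    sunday_multiplier = sunday_multiplier,
    missing_day_prob = missing_day_prob,
    missing_day_dispersion = missing_day_dispersion,
    partial_day_prob = partial_day_prob,
    bmi_effect_log = bmi_effect_log,
    bmi_class_effect = bmi_class_effect,
    group_effect_steps = group_effect_steps,
    covariate_model = covariate_model,
    activation_range = as.Date(activation_range),
    seed = seed
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
}

#' Default covariate model of the synthetic cohort
#'
#' Per-disease-group distributions of the baseline covariates carried by the
#' generator: sex, age, BMI, disease duration, biologic therapy, employment,
#' patient global assessment (PtGA, 0-10) and the disease-specific activity
#' score (DAS28 for RA, BASDAI for axSpA). Values emulate a published
#' RA/axSpA tracker cohort (RA patients older and predominantly female).
#'
#' @param prop_ra Fraction of participants with RA (vs axSpA).
#' @return A named list, one element per group plus `prop_ra`.
#' @export
covariate_model_defaults <- function(prop_ra = 83 / 157) {
  list(
    prop_ra = prop_ra,
    RA = list(
      female_p = 0.831, age_mean = 49.9, age_sd = 12.9,
      bmi_mean = 24.9, bmi_sd = 4.4,
      duration_mean = 10.7, duration_sd = 8.8,
      biologic_p = 0.506, employed_p = 0.711,
      ptga_mean = 3.1, ptga_sd = 2.3,
      score_mean = 2.3, score_sd = 1.2 # DAS28
    ),
    axSpA = list(
      female_p = 0.419, age_mean = 41.3, age_sd = 10.4,
      bmi_mean = 25.3, bmi_sd = 4.6,
      duration_mean = 10.4, duration_sd = 9.1,
      biologic_p = 0.622, employed_p = 0.824,
      ptga_mean = 3.7, ptga_sd = 2.5,
      score_mean = 3.2, score_sd = 2.1 # BASDAI
    )
  )
}

validate_cohort_spec <- function(spec) {
  fail <- function(field, msg) {
    at_abort(sprintf("invalid cohort_spec field `%s`: %s", field, msg),
             "actitraj_spec_error", field = field)
  }
  n <- spec$n_participants
  if (length(n) != 1 || is.na(n) || n < 0 || n != floor(n)) {
    fail("n_participants", "must be a single non-negative integer")
  }
  p <- spec$class_proportions
  if (length(p) != 3 || any(p < 0)) {
    fail("class_proportions", "must be 3 non-negative fractions")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    fail("class_proportions", sprintf("must sum to 1 (got %.12f)", sum(p)))
  }
  for (f in c("class_mvpa_means", "class_mvpa_sds", "class_daily_steps_means")) {
    if (length(spec[[f]]) != 3 || any(spec[[f]] < 0) || any(is.na(spec[[f]]))) {
      fail(f, "must be 3 non-negative values")
    }
  }
  for (f in c("class_daily_steps_sd", "mvpa_day_cv", "steps_day_cv",
              "missing_day_dispersion")) {
    if (length(spec[[f]]) != 1 || is.na(spec[[f]]) || spec[[f]] < 0) {
      fail(f, "must be a single non-negative value")
    }
  }
  for (f in c("missing_day_prob", "partial_day_prob")) {
    v <- spec[[f]]
    if (length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      fail(f, "must be a probability in [0, 1]")
    }
  }
  for (f in c("bmi_effect_log", "bmi_class_effect", "group_effect_steps")) {
    if (length(spec[[f]]) != 1 || !is.finite(spec[[f]])) {
      fail(f, "must be a single finite number")
    }
  }
  sm <- spec$sunday_multiplier
  if (length(sm) != 1 || is.na(sm) || sm <= 0 || sm > 1) {
    fail("sunday_multiplier", "must be in (0, 1]")
  }
  if (length(spec$seed) != 1 || is.na(spec$seed)) fail("seed", "must be a single integer")
  if (length(spec$activation_range) != 2 || any(is.na(spec$activation_range))) {
    fail("activation_range", "must be two parseable dates")
  }
  cm <- spec$covariate_model
  if (!is.list(cm) || is.null(cm$prop_ra) || cm$prop_ra < 0 || cm$prop_ra > 1) {
    fail("covariate_model", "must contain prop_ra in [0, 1]")
  }
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  participants: %d   seed: %s\n", x$n_participants, format(x$seed)))
  cat(sprintf("  MVPA classes (min/day): %s in proportions %s\n",
              paste(x$class_mvpa_means, collapse = "/"),
              paste(x$class_proportions, collapse = "/")))
  cat(sprintf("  steps/day classes: %s (SD %s)\n",
              paste(x$class_daily_steps_means, collapse = "/"),
              x$class_daily_steps_sd))
  cat(sprintf("  missing day p = %.3f (dispersion %.1f), partial day p = %.3f\n",
              x$missing_day_prob, x$missing_day_dispersion, x$partial_day_prob))
  cat(sprintf("  sunday multiplier %.2f, BMI log-effect %.3f/unit\n",
              x$sunday_multiplier, x$bmi_effect_log))
  invisible(x)
}

#' Step-cadence thresholds
#'
#' Cadence (steps per minute) cut-offs used to classify each recorded minute:
#' below `rest` is rest, at least `mvpa` is moderate-to-vigorous activity,
#' and at least `vigorous` is vigorous activity. All comparisons downstream
#' are inclusive (`>=`).
#'
#' @param rest Minimum cadence for a minute to count as active (default 20).
#' @param mvpa Minimum cadence for moderate-to-vigorous activity (default 100).
#' @param vigorous Minimum cadence for vigorous activity (default 130).
#' @return A `cadence_thresholds` object.
#' @export
#' @examples
#' cadence_thresholds()
cadence_thresholds <- function(rest = 20, mvpa = 100, vigorous = 130) {
  if (!(rest < mvpa && mvpa < vigorous)) {
    at_abort("cadence thresholds must satisfy rest < mvpa < vigorous",
             "actitraj_spec_error")
  }
  structure(list(rest = rest, mvpa = mvpa, vigorous = vigorous),
            class = "cadence_thresholds")
}

#' @export
print.cadence_thresholds <- function(x, ...) {
  cat(sprintf("<cadence_thresholds> rest >= %g, mvpa >= %g, vigorous >= %g steps/min\n",
              x$rest, x$mvpa, x$vigorous))
  invisible(x)
}
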