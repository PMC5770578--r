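#' Configuration for the end-to-end tracker analysis pipeline
#'
#' Exactly one input source must be given: a [cohort_spec()] (synthetic
#' cohort, generated at run time) or a directory of step streams and
#' covariates as written by [write_cohort()].
#'
#' @param cohort A [cohort_spec()], or `NULL`.
#' @param input_dir Directory readable by [read_cohort()], or `NULL`.
#' @param thresholds [cadence_thresholds()].
#' @param min_days Adherence threshold: minimum complete days (default 60).
#' @param min_span Full-day rule span in minutes (default 480).
#' @param feature Daily feature to cluster (default `"mvpa_minutes"`).
#' @param k Number of trajectory clusters for the main analysis (default 3).
#' @param n_starts Random starts for the clustering (default 20).
#' @param cluster_on `"imputed"` (default) or `"observed"` matrix for the
#'   main clustering (`"observed"` clusters the incomplete matrix with
#'   available-case distances); the other matrix is always fitted too and
#'   the assignment agreement between the two is reported as a sensitivity
#'   diagnostic.
#' @param weekly Weekly MVPA aggregation (see [participant_summary()]).
#' @param covariates Adjustment covariates for the mixed models.
#' @param seed Seed for the clustering stage (generation uses the seed
#'   inside the cohort spec).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(cohort = NULL, input_dir = NULL,
                            thresholds = cadence_thresholds(),
                            min_days = 60, min_span = 480,
                            feature = "mvpa_minutes", k = 3, n_starts = 20,
                            cluster_on = c("imputed", "observed"),
                            weekly = c("daily_mean_x7", "calendar_week"),
                            covariates = c("sex", "age", "bmi",
                                           "disease_duration", "biologic",
                                           "employed", "ptga"),
                            lmm_engine = c("nlme", "lmer"),
                            lmm_var_power = c("auto", "always", "never"),
                            seed = 1L) {
  if (is.null(cohort) == is.null(input_dir)) {
    at_abort("exactly one of `cohort` (a cohort_spec) or `input_dir` must be given",
             "actitraj_spec_error")
  }
  if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_spec"))
  structure(list(cohort = cohort, input_dir = input_dir,
                 thresholds = thresholds, min_days = min_days,
                 min_span = min_span, feature = feature, k = k,
                 n_starts = n_starts, cluster_on = match.arg(cluster_on),
                 weekly = match.arg(weekly), covariates = covariates,
                 lmm_engine = match.arg(lmm_engine),
                 lmm_var_power = match.arg(lmm_var_power),
                 seed = seed),
            class = "pipeline_config")
}

#' Run the full tracker-cohort analysis pipeline
#'
#' Executes ingest -> validity filtering -> daily patterns -> WHO scoring ->
#' adherence -> trajectory matrix -> weekday-mean imputation -> K-means
#' trajectory clustering -> cluster profiling -> mixed-model and logistic
#' group inference, and collects cohort-level summary tables. Fully
#' deterministic for a fixed configuration (generation seed in the cohort
#' spec, clustering seed in the config).
#'
#' @param config A [pipeline_config()].
#' @return An object of class `study_report`; see Details. When the
#'   adherence filter leaves no analyzable participant the report carries
#'   an explicit `notice` and empty tables instead of models.
#' @details The report contains: `flowchart` (included / analyzable /
#'   excluded counts), `cohort_table` (baseline covariates by group),
#'   `patterns_table` (activity patterns by group with the mixed-model
#'   group p-values and fulfillment fractions), `cluster_profile`,
#'   `cluster_model`, `cluster_agreement` (imputed vs complete-case
#'   assignment agreement), `adherence`, `summary` (per-participant), the
#'   fitted models, and a `manifest` of every parameter.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  if (!is.null(config$cohort)) {
    cohort <- generate_cohort(config$cohort, resolution = "minute")
    steps <- cohort$steps
    covariates <- cohort$covariates
    ground_truth <- cohort$ground_truth
  } else {
    inp <- read_cohort(config$input_dir)
    steps <- inp$steps
    covariates <- inp$covariates
    ground_truth <- NULL
  }

  assembled <- assemble_days(steps, covariates, min_span = config$min_span)
  adherence <- adherence_summary(assembled)
  flt <- filter_adherent(assembled, min_days = config$min_days)
  manifest <- pipeline_manifest(config)

  if (flt$summary$analyzable == 0) {
    return(structure(list(
      notice = sprintf(
        "no participant reached %d complete days; nothing to analyse",
        config$min_days),
      flowchart = flt$summary, adherence = adherence,
      cohort_table = tibble::tibble(), patterns_table = tibble::tibble(),
      cluster_profile = tibble::tibble(), summary = tibble::tibble(),
      manifest = manifest
    ), class = "study_report"))
  }

  features <- daily_features(flt$analyzable, thresholds = config$thresholds)
  summ <- who_status(participant_summary(features, weekly = config$weekly))
  summ <- dplyr::left_join(summ,
                           covariates[, setdiff(names(covariates), "activation_date")],
                           by = "participant_id")

  tm_obs <- trajectory_matrix(features, feature = config$feature,
                              participants = sort(unique(features$participant_id)))
  tm_imp <- impute_missing_days(tm_obs)
  fit_km <- function(x) {
    kmeans_longitudinal(x, k = config$k, n_starts = config$n_starts,
                        seed = config$seed, na_action = "available")
  }
  km <- fit_km(if (config$cluster_on == "imputed") tm_imp else tm_obs)
  km_alt <- fit_km(if (config$cluster_on == "imputed") tm_obs else tm_imp)
  agreement <- mean(km$assignments == km_alt$assignments)

  cluster_profile <- profile_clusters(
    km, summ, covariates,
    feature = feature_summary_col(config$feature))

  day_data <- dplyr::left_join(features, covariates, by = "participant_id")
  # step counts: nlme engine so the power variance function can engage when
  # heteroscedasticity is observed; MVPA minutes: the profiled-likelihood
  # engine (the varPower profile on near-zero fitted counts is numerically
  # fragile and extremely slow, so no variance function there)
  lmm_steps <- fit_group_lmm(day_data, "steps_total", config$covariates,
                             var_power = config$lmm_var_power,
                             engine = config$lmm_engine)
  lmm_mvpa <- fit_group_lmm(day_data, "mvpa_minutes", config$covariates,
                            engine = "lmer")
  who_fit <- try_logistic(fit_who_logistic, summ, covariates)
  low_fit <- try_logistic(fit_low_cluster_logistic, km, covariates)

  structure(list(
    notice = NULL,
    flowchart = flt$summary,
    adherence = adherence,
    cohort_table = cohort_table(covariates, summ$participant_id),
    patterns_table = patterns_table(summ, lmm_steps, lmm_mvpa),
    summary = summ,
    features = features,
    trajectory_matrix = tm_obs,
    trajectory_matrix_imputed = tm_imp,
    cluster_model = km,
    cluster_model_alt = km_alt,
    cluster_agreement = agreement,
    cluster_profile = cluster_profile,
    lmm_steps = lmm_steps,
    lmm_mvpa = lmm_mvpa,
    who_logistic = who_fit,
    low_cluster_logistic = low_fit,
    ground_truth = ground_truth,
    manifest = manifest
  ), class = "study_report")
}

feature_summary_col <- function(feature) {
  switch(feature,
         mvpa_minutes = "mvpa_min_day",
         steps_total = "steps_day",
         active_minutes = "active_min_day",
         vigorous_minutes = "vigorous_min_day",
         morning_fraction = "morning_fraction",
         at_abort(sprintf("no summary column for feature `%s`", feature),
                  "actitraj_input_error"))
}

try_logistic <- function(fun, ...) {
  tryCatch(fun(...), actitraj_error = function(e) e)
}

pipeline_manifest <- function(config) {
  list(
    package_version = as.character(utils::packageVersion("actitraj")),
    seed = config$seed,
    generation_seed = if (!is.null(config$cohort)) config$cohort$seed else NA,
    input = if (is.null(config$input_dir)) "synthetic" else config$input_dir,
    thresholds = unclass(config$thresholds),
    min_days = config$min_days, min_span = config$min_span,
    feature = config$feature, k = config$k, n_starts = config$n_starts,
    cluster_on = config$cluster_on, weekly = config$weekly,
    covariates = config$covariates,
    lmm_engine = config$lmm_engine, lmm_var_power = config$lmm_var_power
  )
}

cohort_table <- function(covariates, analyzable_ids) {
  cov <- covariates[covariates$participant_id %in% analyzable_ids, ]
  dplyr::summarise(
    dplyr::group_by(cov, .data$disease_group),
    n = dplyr::n(),
    female_n = sum(.data$sex == "female"),
    age_mean = mean(.data$age), age_sd = sd(.data$age),
    bmi_mean = mean(.data$bmi), bmi_sd = sd(.data$bmi),
    duration_mean = mean(.data$disease_duration),
    duration_sd = sd(.data$disease_duration),
    employed_n = sum(.data$employed),
    biologic_n = sum(.data$biologic),
    ptga_mean = mean(.data$ptga), ptga_sd = sd(.data$ptga),
    das28_mean = mean(.data$das28, na.rm = TRUE),
    basdai_mean = mean(.data$basdai, na.rm = TRUE),
    .groups = "drop"
  )
}

patterns_table <- function(summ, lmm_steps, lmm_mvpa) {
  by_grp <- dplyr::summarise(
    dplyr::group_by(summ, .data$disease_group),
    n = dplyr::n(),
    active_min_day_mean = mean(.data$active_min_day),
    active_min_day_sd = sd(.data$active_min_day),
    mvpa_min_day_mean = mean(.data$mvpa_min_day),
    mvpa_min_day_sd = sd(.data$mvpa_min_day),
    steps_day_mean = mean(.data$steps_day),
    steps_day_sd = sd(.data$steps_day),
    morning_pct_mean = mean(.data$morning_fraction) * 100,
    morning_pct_sd = sd(.data$morning_fraction) * 100,
    who_mvpa_met_n = sum(.data$who_mvpa_met),
    steps10k_met_n = sum(.data$steps10k_met),
    steps7k_met_n = sum(.data$steps7k_met),
    .groups = "drop"
  )
  attr(by_grp, "group_p_steps") <- lmm_steps$group_p
  attr(by_grp, "group_p_mvpa") <- lmm_mvpa$group_p
  by_grp
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  if (!is.null(x$notice)) {
    cat("  NOTICE:", x$notice, "\n")
    print(x$flowchart)
    return(invisible(x))
  }
  f <- x$flowchart
  cat(sprintf("  flowchart: %d included = %d analyzable + %d excluded (>= %d complete days)\n",
              f$included, f$analyzable, f$excluded, f$min_days))
  cat(sprintf("  adherence: worn %.1f days on average (%.0f%% of days)\n",
              x$adherence$mean_days_worn, x$adherence$mean_pct_days_worn))
  s <- x$summary
  cat(sprintf("  activity: %.0f steps/day, %.1f MVPA min/day, %.1f%% meet >=150 MVPA min/week\n",
              mean(s$steps_day), mean(s$mvpa_min_day), 100 * mean(s$who_mvpa_met)))
  cp <- x$cluster_profile
  cat(sprintf("  clusters (%s): %s\n", x$manifest$feature,
              paste(sprintf("%d/%d (%.1f%%) mean %.1f", cp$cluster, f$analyzable,
                            100 * cp$proportion, cp$feature_mean), collapse = "; ")))
  cat(sprintf("  imputed vs complete-case cluster agreement: %.1f%%\n",
              100 * x$cluster_agreement))
  invisible(x)
}

#' Persist a study report as plain-text tables
#'
#' Writes the report's summary tables as CSV files plus a JSON manifest.
#' Output is byte-identical across runs with the same configuration.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    readr::write_csv(df, file.path(dir, paste0(name, ".csv")), progress = FALSE)
  }
  w(report$flowchart, "flowchart")
  w(report$adherence, "adherence")
  if (is.null(report$notice)) {
    w(report$cohort_table, "cohort_table")
    w(report$patterns_table, "patterns_table")
    w(report$cluster_profile, "cluster_profile")
    w(report$summary, "participant_summary")
    w(tibble::tibble(participant_id = names(report$cluster_model$assignments),
                     cluster = as.integer(report$cluster_model$assignments)),
      "cluster_assignments")
    models <- list(
      lmm_steps = report$lmm_steps$tidy, lmm_mvpa = report$lmm_mvpa$tidy,
      who_logistic = if (inherits(report$who_logistic, "logistic_fit"))
        report$who_logistic$tidy,
      low_cluster_logistic = if (inherits(report$low_cluster_logistic, "logistic_fit"))
        report$low_cluster_logistic$tidy
    )
    for (nm in names(models)) if (!is.null(models[[nm]])) w(models[[nm]], nm)
  } else {
    writeLines(report$notice, file.path(dir, "NOTICE.txt"))
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
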