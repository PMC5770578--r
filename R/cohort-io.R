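#' Write a generated cohort to disk
#'
#' Writes one minute-stream CSV per participant (`streams/<id>.csv`, header
#' `timestamp,steps`, ISO-8601 minute timestamps), the covariate table
#' (`covariates.csv`), the ground truth (`ground_truth.json`, kept in a
#' separate file so analysis stages cannot accidentally consume labels) and
#' the generating parameters (`cohort_spec.yaml`). The file set round-trips
#' through [read_cohort()].
#'
#' @param cohort A minute-resolution [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "step_cohort"))
  if (cohort$resolution != "minute") {
    at_abort("only minute-resolution cohorts can be written as step streams",
             "actitraj_input_error")
  }
  dir.create(file.path(dir, "streams"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    at_abort(sprintf("cannot create output directory: %s", dir), "actitraj_io_error")
  }

  for (id in cohort$covariates$participant_id) {
    s <- cohort$steps[cohort$steps$participant_id == id, c("timestamp", "steps")]
    s$timestamp <- format(s$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    readr::write_csv(s, file.path(dir, "streams", paste0(id, ".csv")),
                     progress = FALSE)
  }
  readr::write_csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   progress = FALSE)
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"), digits = NA)
  sp <- cohort$spec
  sp$activation_range <- as.character(sp$activation_range)
  sp$covariate_model <- rapply(sp$covariate_model, identity, how = "list")
  yaml::write_yaml(unclass(sp), file.path(dir, "cohort_spec.yaml"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `streams/` and `covariates.csv`.
#' @return A list with `steps` (all participants' validated minute records
#'   bound together) and `covariates`.
#' @export
read_cohort <- function(dir) {
  cov_path <- file.path(dir, "covariates.csv")
  if (!file.exists(cov_path)) {
    at_abort(sprintf("no covariates.csv under %s", dir), "actitraj_io_error")
  }
  covariates <- readr::read_csv(
    cov_path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      disease_group = readr::col_character(),
      sex = readr::col_character(),
      biologic = readr::col_logical(),
      employed = readr::col_logical(),
      activation_date = readr::col_date(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  files <- list.files(file.path(dir, "streams"), pattern = "\\.csv$",
                      full.names = TRUE)
  steps <- dplyr::bind_rows(lapply(files, read_step_stream))
  if (nrow(steps) == 0) {
    steps <- tibble::tibble(participant_id = character(),
                            timestamp = as.POSIXct(character(), tz = "UTC"),
                            steps = integer())
  }
  list(steps = steps, covariates = covariates)
}
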