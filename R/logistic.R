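#' Adjusted logistic regression for WHO recommendation fulfillment
#'
#' Models the probability of meeting the physical-activity recommendation
#' as a function of disease group, adjusted for the standard baseline
#' covariates, and reports adjusted odds ratios with 95% Wald confidence
#' intervals. BMI is reported per 5-unit increase.
#'
#' @param status A [who_status()] tibble (or any table with the outcome).
#' @param covariates Covariate table keyed by `participant_id`.
#' @param outcome Logical outcome column (default `"who_mvpa_met"`).
#' @param terms Model terms; defaults to the arthritis-cohort adjustment
#'   set (disease group, sex, age, BMI, disease duration, biologic,
#'   employment, PtGA).
#' @param rescale Named list mapping a term to the unit increase its OR is
#'   expressed for (default: BMI per 5 units).
#' @return A `logistic_fit` object; see [fit_logistic_core()].
#' @export
fit_who_logistic <- function(status, covariates, outcome = "who_mvpa_met",
                             terms = c("disease_group", "sex", "age", "bmi",
                                       "disease_duration", "biologic",
                                       "employed", "ptga"),
                             rescale = list(bmi = 5)) {
  df <- dplyr::inner_join(status[, c("participant_id", outcome)],
                          covariates, by = "participant_id")
  fit_logistic_core(df, outcome, terms, rescale)
}

#' Risk factors for low-activity trajectory cluster membership
#'
#' Multivariable logistic regression of membership in the lowest-activity
#' trajectory cluster (cluster 1 after relabelling) on the baseline
#' covariates. Following the reporting conventions of the field: age enters
#' dichotomized at 60 years, and the BMI odds ratio is expressed per
#' 5-unit increase.
#'
#' @param model A [kmeans_longitudinal()] fit.
#' @param covariates Covariate table keyed by `participant_id`.
#' @param terms Model terms (defaults include `age_ge60`, derived here).
#' @param rescale Named list of per-unit rescalings (default BMI per 5).
#' @return A `logistic_fit` object.
#' @export
fit_low_cluster_logistic <- function(model, covariates,
                                     terms = c("disease_group", "sex",
                                               "age_ge60", "bmi",
                                               "disease_duration", "employed",
                                               "biologic", "ptga"),
                                     rescale = list(bmi = 5)) {
  ids <- names(model$assignments)
  low <- model$assignments == 1L
  if (!any(low) || all(low)) {
    at_abort("low-activity cluster is empty (or is the whole cohort)",
             "actitraj_input_error")
  }
  df <- tibble::tibble(participant_id = ids, low_cluster = unname(low))
  df <- dplyr::inner_join(df, covariates, by = "participant_id")
  if (nrow(df) < length(ids)) {
    at_abort(sprintf("participant %s has no covariate row",
                     setdiff(ids, covariates$participant_id)[1]),
             "actitraj_input_error")
  }
  if ("age_ge60" %in% terms && !"age_ge60" %in% names(df)) {
    df$age_ge60 <- df$age >= 60
  }
  fit_logistic_core(df, "low_cluster", terms, rescale)
}

#' Core adjusted logistic regression with Wald odds-ratio intervals
#'
#' Shared fitting engine of [fit_who_logistic()] and
#' [fit_low_cluster_logistic()]. Degenerate designs are surfaced rather
#' than silently dropped: a single-class outcome errors; aliased
#' (collinear) terms and quasi-separation set diagnostic flags on the
#' result.
#'
#' @param data Modelling frame containing `outcome` and all `terms`.
#' @param outcome Logical (or 0/1) outcome column.
#' @param terms Character vector of predictor columns.
#' @param rescale Named list: term -> unit increase for the reported OR
#'   (the OR for `c` units is `exp(c * beta)`).
#' @return An object of class `logistic_fit`: `tidy` (term, estimate =
#'   log-odds per original unit, std.error, `or`, `ci_low`, `ci_high`,
#'   `p.value`, `or_units`), `collinear` (aliased terms), `separation`
#'   flag, `n`, `n_events`, `model`.
#' @export
fit_logistic_core <- function(data, outcome, terms, rescale = list()) {
  miss <- setdiff(c(outcome, terms), names(data))
  if (length(miss) > 0) {
    at_abort(sprintf("column `%s` not found", miss[1]), "actitraj_input_error")
  }
  df <- data[complete.cases(data[, c(outcome, terms)]), ]
  y <- as.logical(df[[outcome]])
  if (length(unique(y)) < 2) {
    at_abort(sprintf("outcome `%s` has a single class; cannot fit", outcome),
             "actitraj_input_error")
  }
  fml <- stats::reformulate(terms, outcome)
  warned_sep <- FALSE
  fit <- withCallingHandlers(
    glm(fml, data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        warned_sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  cf <- summary(fit)$coefficients
  aliased <- names(which(is.na(coef(fit))))
  est <- cf[, 1]; se <- cf[, 2]; p <- cf[, 4]
  separation <- warned_sep || any(se > 10) || any(abs(est) > 15)

  term_names <- rownames(cf)
  units <- unname(vapply(term_names, function(tn) {
    hit <- names(rescale)[vapply(names(rescale), function(r) grepl(r, tn, fixed = TRUE),
                                 logical(1))]
    if (length(hit) > 0) rescale[[hit[1]]] else 1
  }, numeric(1)))

  z <- qnorm(0.975)
  tidy <- tibble::tibble(
    term = term_names,
    estimate = est, std.error = se,
    or = exp(units * est),
    ci_low = exp(units * est - z * units * se),
    ci_high = exp(units * est + z * units * se),
    p.value = p,
    or_units = units
  )
  out <- list(
    tidy = tidy[tidy$term != "(Intercept)", ],
    intercept = est[["(Intercept)"]],
    collinear = aliased,
    separation = separation,
    n = nrow(df), n_events = sum(y),
    outcome = outcome, model = fit
  )
  class(out) <- "logistic_fit"
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> %s: %d events / %d participants\n",
              x$outcome, x$n_events, x$n))
  if (length(x$collinear) > 0) {
    cat("  collinear (aliased) terms:", paste(x$collinear, collapse = ", "), "\n")
  }
  if (x$separation) cat("  warning: quasi-separation suspected\n")
  df <- x$tidy
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-28s OR %.2f (%.2f-%.2f), p = %.3g%s\n",
                df$term[i], df$or[i], df$ci_low[i], df$ci_high[i], df$p.value[i],
                ifelse(df$or_units[i] != 1,
                       sprintf(" [per %g units]", df$or_units[i]), "")))
  }
  invisible(x)
}
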