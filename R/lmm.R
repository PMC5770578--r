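#' Longitudinal group comparison by linear mixed model
#'
#' Compares a daily activity feature between disease groups over the 90-day
#' window with a linear mixed-effects model: fixed effects for disease
#' group, day index and baseline covariates; random intercept and random
#' day slope per participant; restricted maximum likelihood. With the
#' `"nlme"` engine, heteroscedasticity can be modelled by the power
#' variance function (residual SD proportional to a power of the fitted
#' mean); by default the variance function is switched on only when
#' observed — a significant slope (alpha 0.05) of |residual| on fitted
#' values in the homoscedastic fit triggers the refit.
#'
#' @param data Day-level tibble: one row per participant-day with the
#'   response, `participant_id`, `day_index`, `disease_group`, and any
#'   covariates.
#' @param response Name of the response column (e.g. `"steps_total"`).
#' @param covariates Character vector of covariate columns (may be empty).
#' @param group,id,day Column names of the group factor, participant id and
#'   day index.
#' @param var_power `"auto"` (test-then-refit, default), `"always"`,
#'   `"never"`. Only used by the nlme engine.
#' @param random_slope Include the per-participant random day slope
#'   (default `TRUE`). With `FALSE` only the random intercept remains; in
#'   the degenerate limit of one observation per participant the
#'   fixed-effect estimates then coincide with ordinary least squares.
#' @param engine `"nlme"` (default; supports the power variance function)
#'   or `"lmer"` (lmerTest; much faster, used for replicated simulations).
#' @return An object of class `lmm_fit`: `tidy` (fixed-effect table),
#'   `group_term`, `group_p` (headline comparison), `var_power_used`,
#'   `var_power_theta`, `converged`, `n_participants`, `n_obs`, `engine`,
#'   and the underlying `model` (or `NULL` on failure).
#' @export
fit_group_lmm <- function(data, response, covariates = character(),
                          group = "disease_group", id = "participant_id",
                          day = "day_index",
                          var_power = c("auto", "always", "never"),
                          engine = c("nlme", "lmer"), random_slope = TRUE) {
  var_power <- match.arg(var_power)
  engine <- match.arg(engine)
  need <- c(response, group, id, day, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    at_abort(sprintf("column `%s` not found in day-level data", miss[1]),
             "actitraj_input_error")
  }
  df <- data[, need]
  df <- df[complete.cases(df), ]
  df[[group]] <- factor(df[[group]])
  if (nlevels(df[[group]]) < 2) {
    at_abort("need at least 2 disease groups", "actitraj_input_error")
  }
  per_group <- table(unique(df[, c(id, group)])[[group]])
  if (any(per_group < 2)) {
    at_abort("each group needs at least 2 participants", "actitraj_input_error")
  }

  fixed <- stats::reformulate(c(group, day, covariates), response)
  n_part <- length(unique(df[[id]]))
  n_obs <- nrow(df)

  if (engine == "lmer") {
    ranef <- if (random_slope) paste("(1 +", day, "|", id, ")") else
      paste("(1 |", id, ")")
    fml <- stats::as.formula(
      paste(response, "~", paste(c(group, day, covariates), collapse = " + "),
            "+", ranef))
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lmerTest::lmer(fml, data = df,
                       control = lme4::lmerControl(calc.derivs = FALSE,
                                                   check.conv.singular = "ignore")))),
      error = function(e) e)
    if (inherits(fit, "error")) {
      return(lmm_failure(fit, engine, n_part, n_obs))
    }
    tt <- as.data.frame(summary(fit)$coefficients)
    tidy <- tibble::tibble(
      term = rownames(tt), estimate = tt$Estimate,
      std.error = tt$`Std. Error`, df = tt$df,
      statistic = tt$`t value`, p.value = tt$`Pr(>|t|)`
    )
    vp_used <- FALSE
    theta <- NA_real_
  } else {
    ctrl <- nlme::lmeControl(opt = "optim", maxIter = 100, msMaxIter = 200,
                             returnObject = TRUE)
    random <- if (random_slope) {
      stats::as.formula(paste("~1 +", day, "|", id))
    } else {
      stats::as.formula(paste("~1 |", id))
    }
    base_fit <- tryCatch(
      suppressWarnings(nlme::lme(fixed, data = df, random = random,
                                 method = "REML", control = ctrl)),
      error = function(e) e)
    if (inherits(base_fit, "error")) {
      return(lmm_failure(base_fit, engine, n_part, n_obs))
    }
    use_vp <- switch(var_power,
                     never = FALSE,
                     always = TRUE,
                     auto = heteroscedasticity_observed(base_fit))
    fit <- base_fit
    vp_used <- FALSE
    theta <- NA_real_
    if (use_vp) {
      vp_fit <- tryCatch(
        suppressWarnings(nlme::lme(fixed, data = df, random = random,
                                   weights = nlme::varPower(),
                                   method = "REML", control = ctrl)),
        error = function(e) e)
      if (!inherits(vp_fit, "error")) {
        fit <- vp_fit
        vp_used <- TRUE
        theta <- as.numeric(coef(fit$modelStruct$varStruct,
                                 unconstrained = FALSE))
      }
    }
    tt <- summary(fit)$tTable
    tidy <- tibble::tibble(
      term = rownames(tt), estimate = tt[, "Value"],
      std.error = tt[, "Std.Error"], df = tt[, "DF"],
      statistic = tt[, "t-value"], p.value = tt[, "p-value"]
    )
  }

  grp_rows <- grep(paste0("^", group), tidy$term)
  out <- list(
    tidy = tidy,
    group_term = tidy$term[grp_rows],
    group_estimate = unname(tidy$estimate[grp_rows][1]),
    group_p = unname(tidy$p.value[grp_rows][1]),
    var_power_used = vp_used, var_power_theta = theta,
    converged = TRUE, diagnostics = NULL,
    n_participants = n_part, n_obs = n_obs,
    response = response, engine = engine, model = fit
  )
  class(out) <- "lmm_fit"
  out
}

# |pearson residual| against fitted slope test at alpha = 0.05
heteroscedasticity_observed <- function(fit, alpha = 0.05) {
  r <- abs(resid(fit, type = "response"))
  f <- fitted(fit)
  sl <- tryCatch(summary(lm(r ~ f))$coefficients, error = function(e) NULL)
  !is.null(sl) && nrow(sl) >= 2 && sl[2, 4] < alpha
}

lmm_failure <- function(err, engine, n_part, n_obs) {
  out <- list(
    tidy = tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric(), df = numeric(),
                          statistic = numeric(), p.value = numeric()),
    group_term = character(), group_estimate = NA_real_, group_p = NA_real_,
    var_power_used = FALSE, var_power_theta = NA_real_,
    converged = FALSE, diagnostics = conditionMessage(err),
    n_participants = n_part, n_obs = n_obs,
    response = NA_character_, engine = engine, model = NULL
  )
  class(out) <- "lmm_fit"
  out
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s on %d observations from %d participants (%s)\n",
              x$response, x$n_obs, x$n_participants, x$engine))
  if (!x$converged) {
    cat("  NOT CONVERGED:", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat(sprintf("  group effect %s: estimate %.2f, p = %.3g\n",
              x$group_term[1], x$group_estimate, x$group_p))
  if (x$var_power_used) {
    cat(sprintf("  power variance function applied (theta = %.3f)\n",
                x$var_power_theta))
  }
  invisible(x)
}
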