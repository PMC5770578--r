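#' Design sample size for comparing two means
#'
#' Number of analyzable participants needed per group to detect a
#' difference `delta` between two group means with common standard
#' deviation `sd`, two-sided significance level `sig_level` and power
#' `power`, using the normal-approximation formula
#' `n = ceiling(2 * ((z[1 - alpha/2] + z[power]) * sd / delta)^2)`
#' (floored at 1). A t-based iteration is offered as an alternative.
#'
#' With the design values of a 90-day tracker study in inflammatory
#' arthritis — detectable difference 1500 steps/day, SD 3300, 80% power,
#' 5% alpha — the formula gives 76 participants per group.
#'
#' @param delta Detectable difference between group means (> 0).
#' @param sd Common standard deviation (> 0).
#' @param power Target power (0 < power < 1), default 0.80.
#' @param sig_level Two-sided alpha (0 < alpha < 1), default 0.05.
#' @param method `"normal"` (default) or `"t"` (iterates the central-t
#'   quantiles to a fixed point).
#' @return Integer: participants per group.
#' @export
#' @examples
#' sample_size_two_means(1500, 3300) # 76
sample_size_two_means <- function(delta, sd, power = 0.80, sig_level = 0.05,
                                  method = c("normal", "t")) {
  method <- match.arg(method)
  bad <- function(field, msg) {
    at_abort(sprintf("invalid power specification `%s`: %s", field, msg),
             "actitraj_spec_error", field = field)
  }
  if (!is.finite(sd) || sd <= 0) bad("sd", "must be > 0")
  if (is.na(delta) || delta <= 0) bad("delta", "must be > 0")
  if (!is.finite(power) || power <= 0 || power >= 1) bad("power", "must be in (0, 1)")
  if (!is.finite(sig_level) || sig_level <= 0 || sig_level >= 1) {
    bad("sig_level", "must be in (0, 1)")
  }
  if (!is.finite(delta)) return(1L) # infinite effect: a single pair suffices

  n <- max(1, ceiling(2 * ((qnorm(1 - sig_level / 2) + qnorm(power)) * sd / delta)^2))
  if (method == "t") {
    for (i in 1:50) {
      df <- max(2 * n - 2, 1)
      n_new <- max(2, ceiling(2 * ((qt(1 - sig_level / 2, df) + qt(power, df)) *
                                     sd / delta)^2))
      if (n_new == n) break
      n <- n_new
    }
  }
  as.integer(n)
}
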