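#' Kaplan-Meier product-limit fit
#'
#' Fits the product-limit estimator to right-censored survival records.
#' Censored times reduce the risk set without producing steps.
#'
#' @param records data.frame with columns `time` (>= 0) and `event`
#'   (1 = death, 0 = censored).
#' @return data.frame `time`, `n_risk`, `n_event`, `n_censor`, `surv` — one
#'   row per distinct observed time, survival evaluated just after it.
#' @export
km_fit <- function(records) {
  check_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

check_records <- function(records) {
  stopifnot(all(c("time", "event") %in% names(records)))
  if (nrow(records) < 1) stop("at least one survival record is required")
  if (any(records$time < 0)) stop("negative survival times")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0 or 1")
  invisible(records)
}

#' Two-group log-rank test
#'
#' Standard log-rank test with 1 degree of freedom for a difference in
#' survival between two groups.
#'
#' @param records data.frame with `time`, `event` and a `group` column
#'   (two levels).
#' @return List with `chisq`, `p`, `obs`, `exp` (per-group observed and
#'   expected event counts).
#' @export
logrank_test <- function(records) {
  check_records(records)
  records$group <- factor(records$group)
  if (nlevels(records$group) != 2) stop("log-rank test needs two groups")
  if (sum(records$event) < 1) stop("no events in either group")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = records)
  list(chisq = sd_$chisq,
       p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
       obs = sd_$obs, exp = sd_$exp)
}

#' Univariate Cox proportional-hazards estimate
#'
#' Single-covariate partial-likelihood fit (Efron tie handling, Newton
#' iteration) with a Wald 95% confidence interval for the hazard ratio.
#' A fit that fails to converge or has a monotone likelihood (infinite
#' coefficient) is returned with `flagged = TRUE`.
#'
#' @param records data.frame with `time` and `event`.
#' @param covariate numeric or two-level covariate aligned with `records`.
#' @return List with `hr`, `ci` (lower, upper), `p`, `log_hr`, `se`,
#'   `flagged`.
#' @export
cox_univariate <- function(records, covariate) {
  check_records(records)
  if (length(unique(covariate)) < 2) stop("covariate does not vary")
  if (sum(records$event) < 1) stop("no events")
  x <- if (is.numeric(covariate)) covariate else as.numeric(factor(covariate)) - 1
  d <- data.frame(time = records$time, event = records$event, x = x)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                         ties = "efron",
                         control = survival::coxph.control(iter.max = 50))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  flagged <- !is.finite(beta) || !is.finite(se) || se > 100 ||
    fit$iter >= 50
  z <- beta / se
  list(hr = exp(beta),
       ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
       p = 2 * stats::pnorm(-abs(z)),
       log_hr = beta, se = se, flagged = flagged)
}

#' Optimal survival cutpoint (maximally selected log-rank statistic)
#'
#' Dichotomises a continuous score at the value that maximizes the
#' standardized two-group log-rank statistic, scanning midpoints between
#' consecutive distinct scores that leave at least `minprop` of the samples
#' on each side. This reproduces the usual "optimal cut-point" survival
#' stratification; because the cutpoint is selected on the same data it is
#' then tested on, downstream p-values are optimistically biased — validate
#' on an independent cohort where possible.
#'
#' @param records data.frame with `time`, `event`, aligned with `scores`.
#' @param scores per-sample numeric scores.
#' @param minprop minimum proportion of samples per side (default 0.1).
#' @return List with `value` (cutpoint), `statistic` (|standardized
#'   log-rank|), `n_low`, `n_high`.
#' @export
surv_cutpoint <- function(records, scores, minprop = 0.1) {
  check_records(records)
  if (length(scores) != nrow(records)) stop("scores and records misaligned")
  if (sum(records$event) < 1) stop("no events")
  u <- sort(unique(scores))
  if (length(u) < 2) stop("scores are constant; no admissible split")
  candidates <- (u[-1] + u[-length(u)]) / 2
  n <- length(scores)
  n_low <- vapply(candidates, function(c) sum(scores <= c), integer(1))
  ok <- n_low >= ceiling(minprop * n) & (n - n_low) >= ceiling(minprop * n)
  if (!any(ok)) stop("no split satisfies the minprop constraint")
  candidates <- candidates[ok]
  stat <- vapply(candidates, function(cut) {
    g <- factor(scores > cut, levels = c(FALSE, TRUE))
    sd_ <- survival::survdiff(survival::Surv(records$time, records$event) ~ g)
    # standardized statistic: signed sqrt of the 1-df chi-square
    sqrt(sd_$chisq)
  }, numeric(1))
  best <- which.max(stat)
  list(value = candidates[best], statistic = stat[best],
       n_low = sum(scores <= candidates[best]),
       n_high = sum(scores > candidates[best]))
}
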