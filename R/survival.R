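#' Construct overall survival from dates
#'
#' Overall survival is the time from diagnosis to any-cause death or the
#' last follow-up; the event indicator is 1 iff death was observed.
#'
#' @param diagnosis_date Date (or numeric) of diagnosis.
#' @param death_date Date of death, `NA` if alive.
#' @param last_followup Date of last follow-up (used when `death_date` is
#'   `NA`).
#' @return Data frame with `time` (years) and `event` (0/1).
#' @export
make_os <- function(diagnosis_date, death_date, last_followup) {
  end <- ifelse(is.na(death_date), as.numeric(last_followup),
                as.numeric(death_date))
  start <- as.numeric(diagnosis_date)
  if (any(is.na(end))) stopf("missing follow-up for alive patients")
  if (any(end < start)) stopf("follow-up precedes diagnosis")
  data.frame(time = (end - start) / 365.25,
             event = as.integer(!is.na(death_date)))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator; the median survival is the earliest time at
#' which the curve reaches 0.5 or below, undefined (`NA`) when it never
#' does.
#'
#' @param times Follow-up times.
#' @param events Event indicators (1 = death, 0 = censored).
#' @return A list of class `surv_curve`: `time`, `n_risk`, `n_event`,
#'   `surv`, `median`.
#' @export
kaplan_meier <- function(times, events) {
  stopifnot(length(times) >= 1L, length(times) == length(events),
            all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  s <- summary(fit, censored = TRUE)
  med <- if (any(fit$surv <= 0.5)) fit$time[which(fit$surv <= 0.5)[1L]]
  else NA_real_
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, surv = fit$surv, median = med),
            class = "surv_curve")
}

#' Log-rank test between survival groups
#'
#' @param group Factor (or vector) of group assignments, >= 2 groups.
#' @inheritParams kaplan_meier
#' @return A `test_result` list with the chi-square statistic, df and p.
#' @export
log_rank <- function(group, times, events) {
  group <- factor(group)
  if (nlevels(group) < 2L) stopf("need at least 2 groups")
  if (sum(events) == 0L) stopf("degenerate data: no events in any group")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- length(sd_$n) - 1L
  test_result(statistic = c(X2 = unname(sd_$chisq)), df = df,
              p.value = pchisq(sd_$chisq, df, lower.tail = FALSE),
              method = "Log-rank test",
              summaries = data.frame(group = levels(group),
                                     n = as.vector(sd_$n),
                                     observed = as.vector(sd_$obs),
                                     expected = as.vector(sd_$exp)))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximisation with the Efron approximation for tied
#' event times. Reports per covariate the coefficient, hazard ratio,
#' Wald 95% CI `exp(beta +/- 1.96 SE)` and p.
#'
#' @param design Data frame of covariates (complete cases are used).
#' @param times,events Follow-up times and event indicators.
#' @param ties Tie handling, default `"efron"`.
#' @return A list of class `cox_fit` with `coefficients` (data frame:
#'   `term`, `beta`, `se`, `hr`, `ci_lo`, `ci_hi`, `p.value`), `n`,
#'   `n_events`, `converged`.
#' @export
cox_fit <- function(design, times, events, ties = "efron") {
  stopifnot(is.data.frame(design), nrow(design) == length(times),
            length(times) == length(events))
  ok <- complete.cases(design) & is.finite(times) & !is.na(events)
  design <- design[ok, , drop = FALSE]
  times <- times[ok]; events <- events[ok]
  if (sum(events) == 0) stopf("degenerate data: no events")
  dat <- cbind(design, .time = times, .event = events)
  fit <- tryCatch(
    survival::coxph(survival::Surv(.time, .event) ~ . - .time - .event,
                    data = dat, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w)))
        stopf("non-convergence: monotone likelihood (perfect separation?)")
      suppressWarnings(
        survival::coxph(survival::Surv(.time, .event) ~ . - .time - .event,
                        data = dat, ties = ties))
    })
  if (any(is.na(coef(fit))))
    stopf("collinearity error: terms not estimable: %s",
          paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(0.975)
  coefs <- data.frame(term = names(beta), beta = unname(beta),
                      se = unname(se), hr = exp(unname(beta)),
                      ci_lo = exp(unname(beta) - z * unname(se)),
                      ci_hi = exp(unname(beta) + z * unname(se)),
                      p.value = 2 * pnorm(-abs(unname(beta) / unname(se))),
                      row.names = NULL)
  structure(list(coefficients = coefs, n = fit$n, n_events = fit$nevent,
                 converged = fit$iter < 50, ties = ties, fit = fit),
            class = "cox_fit")
}

#' Univariable Cox fits, one covariate at a time
#'
#' @inheritParams cox_fit
#' @param covariates Character vector of column names of `design` to fit
#'   individually.
#' @return Named list of [cox_fit()] results.
#' @export
cox_univariable <- function(design, times, events, ties = "efron",
                            covariates = names(design)) {
  setNames(lapply(covariates, function(v)
    cox_fit(design[, v, drop = FALSE], times, events, ties)), covariates)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  cf <- x$coefficients
  for (i in seq_len(nrow(cf)))
    cat(sprintf("  %-20s HR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
                cf$term[i], cf$hr[i], cf$ci_lo[i], cf$ci_hi[i],
                cf$p.value[i]))
  invisible(x)
}
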