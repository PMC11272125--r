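test_that("overall survival construction follows the OS definition", {
  os <- make_os(0, 0, NA)                    # death on diagnosis day
  expect_equal(os$time, 0)
  expect_equal(os$event, 1L)
  os2 <- make_os(0, NA, 2.5 * 365.25)        # alive at last follow-up
  expect_equal(os2$time, 2.5)
  expect_equal(os2$event, 0L)
  d <- make_os(0, 365.25, NA)
  c_ <- make_os(0, NA, 365.25)
  expect_equal(d$time, c_$time)
  expect_false(d$event == c_$event)
  expect_error(make_os(100, NA, 50), "precedes")
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)
  # all-event KM equals the empirical survival function
  tt <- c(0.5, 1.2, 2.2, 3.9, 4.4)
  km2 <- kaplan_meier(tt, rep(1, 5))
  expect_equal(km2$surv, 1 - seq_len(5) / 5)

  none <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(none$surv == 1))
  expect_true(is.na(none$median))

  # moving a censoring time later (still after the last event) leaves the
  # curve unchanged at earlier times
  a <- kaplan_meier(c(1, 2, 3), c(1, 1, 0))
  b <- kaplan_meier(c(1, 2, 9), c(1, 1, 0))
  expect_equal(a$surv[1:2], b$surv[1:2])
})

test_that("log-rank observed-minus-expected equals the risk-set tabulation", {
  grp <- rep(c("A", "B"), each = 3)
  tt <- c(1, 3, 5, 2, 4, 6)
  ev <- c(1, 1, 0, 1, 0, 1)
  lr <- log_rank(grp, tt, ev)
  oe_hand <- oracle_logrank_oe(grp, tt, ev)
  oe_pkg <- lr$summaries$observed - lr$summaries$expected
  expect_equal(oe_pkg, unname(oe_hand), tolerance = 1e-10)

  same <- log_rank(rep(c("A", "B"), each = 4),
                   rep(c(1, 2, 3, 4), 2), rep(c(1, 1, 0, 1), 2))
  expect_equal(unname(same$statistic), 0, tolerance = 1e-12)
  expect_equal(same$p.value, 1)
  expect_error(log_rank(grp, tt, rep(0, 6)), "degenerate")
})

test_that("null log-rank rejects at the nominal 5% rate", {
  set.seed(41)
  rej <- mean(vapply(1:1000, function(i) {
    tt <- rexp(60, 0.3)
    cc <- rexp(60, 0.1)
    log_rank(rep(1:2, each = 30), pmin(tt, cc),
             as.integer(tt <= cc))$p.value < 0.05
  }, logical(1L)))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Cox estimates maximise the hand-written partial likelihood", {
  x <- c(1, 1, 1, 0, 0, 0)
  tt <- c(1.1, 2.3, 4.1, 3.2, 5.5, 6.7)
  ev <- c(1, 1, 0, 1, 1, 0)
  fit <- cox_fit(data.frame(x = x), tt, ev)
  opt <- optimize(function(b) -oracle_cox_logpl(b, x, tt, ev),
                  interval = c(-5, 5))
  expect_equal(fit$coefficients$beta, opt$minimum, tolerance = 1e-4)
  expect_true(fit$converged)
  expect_true(fit$coefficients$ci_lo <= fit$coefficients$hr)
  expect_true(fit$coefficients$hr <= fit$coefficients$ci_hi)
})

test_that("Cox is invariant to time scaling and covariate shifts", {
  co <- generate_cohort(cohort_spec(n_patients = 300, seed = 17))
  f1 <- cox_fit(co[, c("til", "sex_man")], co$time, co$event)
  f2 <- cox_fit(co[, c("til", "sex_man")], co$time * 3.7, co$event)
  expect_equal(f1$coefficients$hr, f2$coefficients$hr, tolerance = 1e-8)
  co2 <- co
  co2$til <- co2$til + 100
  f3 <- cox_fit(co2[, c("til", "sex_man")], co$time, co$event)
  expect_equal(f1$coefficients$hr, f3$coefficients$hr, tolerance = 1e-6)
})

test_that("two-group log-rank agrees with the Cox score test", {
  set.seed(42)
  tt <- round(rexp(80, 0.3), 6)              # continuous, no ties
  grp <- rep(0:1, 40)
  ev <- rbinom(80, 1, 0.8)
  lr <- log_rank(grp, tt, ev)
  cx <- survival::coxph(survival::Surv(tt, ev) ~ grp)
  p_score <- pchisq(cx$score, 1, lower.tail = FALSE)
  expect_lt(abs(lr$p.value - p_score), 0.01)
})

test_that("univariable wrappers fit one covariate at a time", {
  co <- generate_cohort(cohort_spec(n_patients = 200, seed = 19))
  uni <- cox_univariable(co[, c("til", "sex_man")], co$time, co$event)
  expect_named(uni, c("til", "sex_man"))
  expect_equal(nrow(uni$til$coefficients), 1L)
  expect_equal(uni$til$coefficients$term, "til")
})

test_that("degenerate Cox inputs are signalled", {
  expect_error(cox_fit(data.frame(x = c(1, 0)), c(1, 2), c(0, 0)),
               "no events")
})
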