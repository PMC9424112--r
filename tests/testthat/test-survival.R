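test_that("product-limit estimate matches the hand computation", {
  # events at 10 and 20, censorings at 15 and 25:
  # S(20) = (1 - 1/4) * (1 - 1/2) = 0.375
  co <- make_cohort(time = c(10, 15, 20, 25), status = c(1, 0, 1, 0),
                    followup = c(60, 60, 60, 60))
  co$transformation_time <- c(10, 15, 20, 25)
  co$followup_time <- c(10, 15, 20, 25)
  co$recurrence_time <- co$followup_time
  km <- km_fit(validate_cohort(co, strict = FALSE), "transformation")
  cv <- km$curves[[1]]
  at20 <- cv$surv[max(which(cv$time <= 20))]
  expect_equal(at20, 0.375, tolerance = 1e-12)
  rk <- km_risk(km, times = 20)
  expect_equal(rk$risk, 0.625, tolerance = 1e-12)
})

test_that("with no censoring KM equals 1 - ECDF; all-censored gives S = 1", {
  set.seed(31)
  t <- sort(ceiling(rexp(40, 0.05)))
  co <- make_cohort(time = t, status = rep(1, 40), followup = pmax(t, 60))
  km <- km_fit(co, "transformation")
  cv <- km$curves[[1]]
  ecdf_t <- ecdf(t)
  ev <- cv$n_event > 0
  expect_equal(cv$surv[ev], 1 - ecdf_t(cv$time[ev]), tolerance = 1e-12)

  co0 <- make_cohort(time = rep(80, 10), status = rep(0, 10))
  expect_warning(km0 <- km_fit(co0, "transformation"), "zero events")
  expect_true(all(km0$curves[[1]]$surv == 1))
  expect_true(km0$curves[[1]]$zero_events)
})

test_that("log-log confidence intervals bracket the estimate within [0, 1]", {
  set.seed(32)
  t <- ceiling(rexp(60, 0.02))
  st <- rbinom(60, 1, 0.7)
  co <- make_cohort(time = pmin(t, 120), status = as.integer(st & t <= 120),
                    followup = pmax(pmin(t, 120), 60))
  km <- km_fit(co, "transformation")
  cv <- km$curves[[1]]
  ok <- !is.na(cv$lower)
  expect_true(all(cv$lower[ok] <= cv$surv[ok] + 1e-12))
  expect_true(all(cv$upper[ok] >= cv$surv[ok] - 1e-12))
  expect_true(all(cv$lower[ok] >= 0 & cv$upper[ok] <= 1))
  expect_true(all(diff(cv$surv) <= 1e-12))      # S non-increasing
  evt <- cv$n_event > 0
  expect_true(all(diff(cv$n_risk[evt]) < 0))    # risk set shrinks over event times
})

test_that("Efron fit equals the exact no-ties partial likelihood", {
  set.seed(33)
  n <- 80
  x <- rbinom(n, 1, 0.4)
  t <- rexp(n, 0.01 * exp(0.8 * x))      # continuous: no ties
  cen <- runif(n, 50, 150)
  time <- pmin(t, cen)
  status <- as.integer(t <= cen)
  co <- make_cohort(time = time, status = status, followup = time)
  fit <- cox_fit(co, "transformation",
                 data.frame(case_id = co$case_id, x = x))
  beta_oracle <- oracle_cox_beta(time, status, x)
  expect_equal(fit$table$coef, beta_oracle, tolerance = 1e-5)
})

test_that("cox_fit validates inputs and is time-scale invariant", {
  co <- make_cohort(time = c(10, 20, 70, 80), status = c(1, 1, 0, 0))
  expect_error(cox_fit(co, "transformation",
                       data.frame(case_id = co$case_id, x = rep(0, 4))),
               class = "oedprog_nonidentifiable")
  expect_error(cox_fit(co, "transformation",
                       data.frame(case_id = co$case_id[1:2], x = c(0, 1))),
               "covariates missing")

  set.seed(34)
  n <- 100
  x <- rbinom(n, 1, 0.5)
  t <- ceiling(rexp(n, 0.02 * exp(x)))
  co <- make_cohort(time = t, status = rep(1, n), followup = pmax(t, 60))
  f1 <- cox_fit(co, "transformation", data.frame(case_id = co$case_id, x = x))
  co2 <- co
  co2$transformation_time <- co$transformation_time * 7
  co2$followup_time <- co$followup_time * 7
  co2$recurrence_time <- co2$followup_time
  f2 <- cox_fit(co2, "transformation", data.frame(case_id = co2$case_id, x = x))
  expect_equal(f1$table$coef, f2$table$coef, tolerance = 1e-9)
})

test_that("hazard-ratio recovery across a grid of true effects", {
  set.seed(35)
  for (hr_true in c(1, 2.5, 5)) {
    est <- replicate(30, {
      n <- 400
      x <- rbinom(n, 1, 0.35)
      t <- rexp(n, 0.004 * hr_true^x)
      time <- pmin(t, 120)
      status <- as.integer(t <= 120)
      co <- make_cohort(time = pmax(time, 1), status = status,
                        followup = pmax(time, 60))
      cox_fit(co, "transformation",
              data.frame(case_id = co$case_id, x = x))$table$hr
    })
    expect_lt(abs(median(est) - hr_true) / hr_true, 0.10)
  }
})

test_that("univariate feature table flags constants and keeps other rows", {
  sim <- generate(generator_config(n_cases = 200, seed = 36))
  prof <- consensus_profile(sim$panel)
  prof$verrucous_surface <- 1L  # constant-present feature
  tab <- univariate_feature_cox(sim$cohort, prof)
  expect_equal(nrow(tab), 24)  # 12 features x 2 events
  vr <- tab[tab$feature == "verrucous_surface", ]
  expect_true(all(is.na(vr$hr)))
  expect_true(all(grepl("non-identifiable", vr$flag)))
  rest <- tab[tab$feature != "verrucous_surface", ]
  expect_true(all(is.finite(rest$hr)))
  expect_equal(rest$significant, rest$p < 0.05)
})

test_that("null features trip the significance flag at roughly the type-I rate", {
  set.seed(37)
  flags <- replicate(150, {
    n <- 120
    x <- rbinom(n, 1, 0.4)
    t <- ceiling(rexp(n, 0.005))
    time <- pmin(t, 120)
    status <- as.integer(t <= 120)
    co <- make_cohort(time = pmax(time, 1), status = status,
                      followup = pmax(time, 60))
    cox_fit(co, "transformation",
            data.frame(case_id = co$case_id, x = x))$table$p < 0.05
  })
  expect_lt(mean(flags), 0.12)
  expect_gt(mean(flags), 0.005)
})
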