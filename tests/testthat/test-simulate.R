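test_that("same seed and config give byte-identical studies", {
  cfg <- generator_config(n_cases = 50, seed = 51)
  s1 <- generate(cfg)
  s2 <- generate(cfg)
  expect_identical(s1$panel$assessments, s2$panel$assessments)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate(cfg, seed = 52)
  expect_false(identical(s1$cohort, s3$cohort))
})

test_that("generated studies always pass cohort and panel validation", {
  for (seed in c(53, 54)) {
    sim <- generate(generator_config(n_cases = 70, seed = seed))
    expect_silent(validate_cohort(sim$cohort, strict = TRUE))
    df <- as.data.frame(sim$panel)
    expect_s3_class(rating_panel(df), "rating_panel")
    expect_equal(nrow(df), 70 * 3 * 12)
  }
})

test_that("perfect raters give unit agreement on variable features", {
  sim <- generate(generator_config(n_cases = 80, sensitivity = 1,
                                   specificity = 1, seed = 55))
  tab <- suppressWarnings(agreement_table(sim$panel))
  expect_true(all(tab$pa == 1))
  expect_true(all(tab$ac1 == 1))
  expect_true(all(tab$complete_agreement_fraction == 1))
})

test_that("pooled feature prevalence converges to the configured values", {
  sim <- generate(generator_config(n_cases = 5000, seed = 56))
  tab <- agreement_table(sim$panel)
  cfg <- sim$config
  for (i in seq_len(nrow(cfg$features))) {
    f <- cfg$features$feature[i]
    pi0 <- cfg$features$prevalence[i]
    # observed prevalence is latent prevalence filtered through rater noise
    expected <- pi0 * mean(cfg$sensitivity) + (1 - pi0) * (1 - mean(cfg$specificity))
    expect_lt(abs(tab$prevalence[tab$feature == f] - expected), 0.02)
  }
})

test_that("null hazard ratios make events independent of the score stratum", {
  fe <- default_feature_params()
  fe$hr_transformation <- 1
  fe$hr_recurrence <- 1
  sim <- generate(generator_config(n_cases = 4000, features = fe, seed = 57))
  prof <- consensus_profile(sim$panel)
  sc <- score_cohort(prof, "six_point")
  strat <- sc$stratum[match(sim$cohort$case_id, sc$case_id)]
  p <- suppressWarnings(
    chisq.test(table(strat, sim$cohort$transformation_event))$p.value)
  expect_gt(p, 0.01)
})

test_that("event rates respond monotonically to the baseline hazard", {
  base <- c(transformation = 0.002, recurrence = 0.003)
  rates <- vapply(c(1, 2, 4), function(mult) {
    cfg <- generator_config(n_cases = 2000, baseline_hazard = base * mult,
                            seed = 58)
    mean(generate(cfg)$cohort$transformation_event)
  }, 0)
  expect_true(all(diff(rates) > 0))
})

test_that("default calibration hits the study-scale event rates", {
  reps <- vapply(1:30, function(s) {
    sim <- generate(generator_config(n_cases = 109, seed = 500 + s))
    c(mean(sim$cohort$transformation_event == 1 &
             sim$cohort$transformation_time <= 60),
      mean(sim$cohort$recurrence_event == 1 &
             sim$cohort$recurrence_time <= 60))
  }, c(0, 0))
  expect_lt(abs(mean(reps[1, ]) - 0.18), 0.04)
  expect_lt(abs(mean(reps[2, ]) - 0.25), 0.04)
})

test_that("zero baseline hazard is flagged as degenerate calibration", {
  cfg <- generator_config(n_cases = 60,
                          baseline_hazard = c(transformation = 0, recurrence = 0),
                          seed = 59)
  sim <- generate(cfg)
  expect_equal(sum(sim$cohort$transformation_event), 0)
  rep <- calibration_report(sim)
  expect_true(rep$degenerate)
})

test_that("invalid config fields are rejected by name", {
  expect_error(generator_config(sensitivity = 1.2), "sensitivity")
  expect_error(generator_config(n_cases = 0), "n_cases")
  expect_error(generator_config(early_censor_fraction = -0.1),
               "early_censor_fraction")
  expect_error(generator_config(site_probs = c(tongue = 1, gingivae = 0.5)),
               "site_probs")
  fe <- default_feature_params()
  fe$prevalence[1] <- 2
  expect_error(generator_config(features = fe), "prevalence")
})

test_that("severity factor induces positive correlation among scoring features", {
  s0 <- generate(generator_config(n_cases = 4000, severity_sd = 0, seed = 60))
  s1 <- generate(generator_config(n_cases = 4000, severity_sd = 2, seed = 60))
  cor0 <- cor(s0$truth$bulbous_rete_pegs, s0$truth$nuclear_pleomorphism)
  cor1 <- cor(s1$truth$bulbous_rete_pegs, s1$truth$nuclear_pleomorphism)
  expect_lt(abs(cor0), 0.06)
  expect_gt(cor1, 0.15)
})

test_that("calibration report recovers the configured hazard ratios at scale", {
  sim <- generate(generator_config(n_cases = 4000, seed = 61))
  rep <- calibration_report(sim)
  expect_false(rep$degenerate)
  hr <- rep$hr_recovery
  expect_true(!is.null(hr))
  # log-scale agreement within 25% for the six non-null features
  expect_true(all(abs(log(hr$hr / hr$target_hr)) < log(1.25)))
})
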