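test_that("AUROC handles perfect, tied and degenerate predictors", {
  expect_equal(auroc(c(0, 1, 2, 3), c(0, 0, 1, 1))$auc, 1)
  expect_equal(auroc(c(0, 1, 1, 2), c(0, 1, 0, 1))$auc, 0.875)
  expect_equal(auroc(rep(2, 10), c(rep(0, 5), rep(1, 5)))$auc, 0.5)
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "degenerate")
  expect_error(auroc(1:3, c(0, 1)), "lengths differ")
})

test_that("rank AUROC equals brute-force pairwise comparison with tie halves", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(10:60, 1)
    score <- sample(0:6, n, replace = TRUE)
    event <- rbinom(n, 1, 0.4)
    if (sum(event) == 0 || sum(event) == n) next
    expect_equal(auroc(score, event)$auc, oracle_auc(score, event),
                 tolerance = 1e-12)
  }
})

test_that("ROC point set is monotone and spans (0,0) to (1,1)", {
  set.seed(42)
  r <- auroc(rnorm(50), rbinom(50, 1, 0.3))
  expect_true(all(diff(r$points$sensitivity) >= 0))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_equal(r$points$sensitivity[1], 0)
  expect_equal(r$points$sensitivity[nrow(r$points)], 1)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
})

test_that("DeLong self-comparison gives p = 1 exactly and order invariance", {
  set.seed(43)
  y <- rbinom(60, 1, 0.35)
  s <- rnorm(60) + y
  a <- auroc(s, y)
  cmp <- compare_auroc(a, a)
  expect_identical(cmp$p, 1)
  expect_identical(cmp$diff, 0)

  b <- auroc(rnorm(60), y)
  c1 <- compare_auroc(a, b)
  c2 <- compare_auroc(b, a)
  expect_equal(c1$p, c2$p)
  expect_equal(c1$diff, -c2$diff)

  # case order invariance
  perm <- sample(60)
  c3 <- compare_auroc(auroc(s[perm], y[perm]), auroc(b$score[perm], y[perm]))
  expect_equal(c3$p, c1$p, tolerance = 1e-12)
})

test_that("DeLong is invariant to a common monotone transform", {
  set.seed(44)
  y <- rbinom(80, 1, 0.4)
  s1 <- rnorm(80) + y
  s2 <- rnorm(80) + 0.5 * y
  c1 <- compare_auroc(auroc(s1, y), auroc(s2, y))
  c2 <- compare_auroc(auroc(exp(s1), y), auroc(exp(s2), y))
  expect_equal(c1$p, c2$p, tolerance = 1e-12)
  expect_error(compare_auroc(auroc(s1, y), auroc(s2[1:40], y[1:40])),
               "identical cases")
})

test_that("DeLong agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(45)
  for (i in 1:10) {
    y <- rbinom(80, 1, 0.4)
    if (sum(y) < 2 || sum(y) > 78) next
    s1 <- rnorm(80) + y
    s2 <- rnorm(80) + 0.7 * y
    ours <- compare_auroc(auroc(s1, y), auroc(s2, y))
    ref <- pROC::roc.test(pROC::roc(y, s1, quiet = TRUE, direction = "<"),
                          pROC::roc(y, s2, quiet = TRUE, direction = "<"),
                          method = "delong")
    expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-9)
  }
})

test_that("incidence table counts are internally consistent", {
  sim <- generate(generator_config(n_cases = 150, seed = 46))
  prof <- consensus_profile(sim$panel)
  tab <- incidence_table(sim$cohort, prof)
  expect_equal(nrow(tab), 24)
  expect_true(all(tab$n_positive + tab$n_negative == 150))
  ok <- tab$n_positive > 0
  expect_equal(tab$pct_positive[ok],
               100 * tab$events_positive[ok] / tab$n_positive[ok])

  # zero-event cohort: all incidences zero
  co0 <- sim$cohort
  co0$transformation_event <- 0L
  co0$recurrence_event <- 0L
  co0$transformation_time <- co0$followup_time
  co0$recurrence_time <- co0$followup_time
  tab0 <- incidence_table(validate_cohort(co0, strict = FALSE), prof)
  expect_true(all(tab0$events_positive == 0 & tab0$events_negative == 0))

  # all-positive feature: negative arm has NA percentage, not 0
  prof$basal_cell_hyperplasia <- 1L
  tab1 <- incidence_table(sim$cohort, prof)
  expect_true(all(is.na(tab1$pct_negative[tab1$feature == "basal_cell_hyperplasia"])))
})

test_that("augmented score-only model reproduces the raw AUROC", {
  sim <- generate(generator_config(n_cases = 200, seed = 47))
  prof <- consensus_profile(sim$panel)
  sc <- score_cohort(prof, "six_point")
  s <- sc$score[match(sim$cohort$case_id, sc$case_id)]
  raw <- auroc(s, sim$cohort$transformation_event)
  aug <- augmented_model_auroc(sim$cohort, s, character(0), "transformation")
  expect_equal(aug$auc, raw$auc, tolerance = 1e-9)
})

test_that("uninformative covariates leave the AUROC essentially unchanged", {
  set.seed(48)
  sim <- generate(generator_config(n_cases = 2000, seed = 48))
  co <- sim$cohort
  co$age <- rnorm(2000, 60, 10)          # decouple covariates from outcome
  co$gender <- sample(c("male", "female"), 2000, replace = TRUE)
  co <- validate_cohort(co, strict = FALSE)
  prof <- consensus_profile(sim$panel)
  sc <- score_cohort(prof, "six_point")
  s <- sc$score[match(co$case_id, sc$case_id)]
  raw <- auroc(s, co$transformation_event)$auc
  aug <- augmented_model_auroc(co, s, c("age", "gender"), "transformation")$auc
  expect_lt(abs(aug - raw), 0.02)
})

test_that("per-rater evaluation with perfect raters equals consensus", {
  sim <- generate(generator_config(n_cases = 150, sensitivity = 1,
                                   specificity = 1, seed = 49))
  tab <- per_rater_evaluation(sim$panel, sim$cohort)
  expect_equal(nrow(tab), 2 * 2 * 4)  # 2 models x 2 events x (3 raters + consensus)
  for (model in unique(tab$model)) {
    for (ev in unique(tab$event)) {
      sub <- tab[tab$model == model & tab$event == ev, ]
      expect_true(all(abs(sub$auc - sub$auc[sub$source == "consensus"]) < 1e-12))
    }
  }
})
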