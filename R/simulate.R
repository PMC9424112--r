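#' Generator configuration for synthetic OED studies
#'
#' Assembles and validates the parameters of the synthetic-cohort
#' generator. Defaults emulate the 109-case study the package's models
#' were developed on: 3 raters, 12 binary features at the observed
#' pooled prevalences, rater sensitivity/specificity producing
#' moderate agreement, exponential event hazards multiplied per present
#' feature by its hazard ratio (the six prognostic features carry their
#' published point estimates; the rest are null), administrative
#' censoring at 120 months with a uniform early-censoring fraction, and
#' covariate distributions matching the study cohort table.
#'
#' @param n_cases Number of cases (default 109).
#' @param n_raters Number of raters (default 3).
#' @param features Data frame with columns `feature`, `prevalence`,
#'   `hr_transformation`, `hr_recurrence`; default
#'   [default_feature_params()].
#' @param sensitivity,specificity Per-rater probabilities of rating 1
#'   given a present / 0 given an absent latent feature; scalars are
#'   recycled across raters (defaults 0.85 / 0.90).
#' @param baseline_hazard Named vector `c(transformation = , recurrence = )`
#'   of exponential rates per month, or `NA` (default) to solve each
#'   rate so that the marginal event probability by
#'   `target_horizon` months equals `target_event_rate`.
#' @param target_event_rate Named vector of marginal event probabilities
#'   used when `baseline_hazard` is `NA` (defaults 0.18 transformation,
#'   0.25 recurrence, the study's five-year scale).
#' @param target_horizon Horizon in months for the event-rate
#'   calibration (default 60).
#' @param censor_horizon Administrative censoring time in months
#'   (default 120).
#' @param early_censor_fraction Fraction of cases censored at a uniform
#'   time between `min_followup` and `censor_horizon` instead of the
#'   horizon (default 0.15).
#' @param min_followup Minimum follow-up in months for censored cases
#'   (default 60).
#' @param severity_sd Standard deviation of an optional shared latent
#'   severity factor (logit scale) inducing positive correlation among
#'   the six prognostic features; 0 (default) generates features
#'   independently.
#' @param round_times Record event/censoring times in whole months
#'   (ceiling), producing tied times as in registry data (default
#'   `TRUE`).
#' @param prop_male Probability of male gender (default 0.61).
#' @param site_probs Named probabilities over intraoral sites (defaults
#'   from the study cohort).
#' @param treatment_probs Named probabilities over treatments.
#' @param age_mean,age_sd Normal age model (years), truncated to
#'   [18, 95]; defaults 67 / 14.8 reproduce a median 67 (IQR ~57-77).
#' @param grade_probs 3 x 3 matrix of P(mild/moderate/severe) by latent
#'   six-point count group (rows: 0-1, 2-3, 4-6).
#' @param moderate_high_prob Probability that a moderate-grade lesion is
#'   called high on the binary scale (mild is always low, severe always
#'   high; default 0.2).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return Validated list of class `oed_generator_config`.
#' @export
generator_config <- function(n_cases = 109L,
                             n_raters = 3L,
                             features = default_feature_params(),
                             sensitivity = 0.85,
                             specificity = 0.90,
                             baseline_hazard = c(transformation = NA_real_,
                                                 recurrence = NA_real_),
                             target_event_rate = c(transformation = 0.18,
                                                   recurrence = 0.25),
                             target_horizon = 60,
                             censor_horizon = 120,
                             early_censor_fraction = 0.15,
                             min_followup = 60,
                             severity_sd = 0,
                             round_times = TRUE,
                             prop_male = 0.61,
                             site_probs = c("tongue" = 0.40, "floor of mouth" = 0.21,
                                            "buccal mucosa" = 0.16, "gingivae" = 0.06,
                                            "hard palate" = 0.06, "lower lip" = 0.06,
                                            "soft palate" = 0.05),
                             treatment_probs = c(monitored = 0.31, excised = 0.64,
                                                 laser = 0.05),
                             age_mean = 67, age_sd = 14.8,
                             grade_probs = default_grade_probs(),
                             moderate_high_prob = 0.2,
                             seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases), n_raters = as.integer(n_raters),
              features = as.data.frame(features, stringsAsFactors = FALSE),
              sensitivity = rep_len(sensitivity, n_raters),
              specificity = rep_len(specificity, n_raters),
              baseline_hazard = baseline_hazard,
              target_event_rate = target_event_rate,
              target_horizon = target_horizon,
              censor_horizon = censor_horizon,
              early_censor_fraction = early_censor_fraction,
              min_followup = min_followup,
              severity_sd = severity_sd,
              round_times = isTRUE(round_times),
              prop_male = prop_male, site_probs = site_probs,
              treatment_probs = treatment_probs,
              age_mean = age_mean, age_sd = age_sd,
              grade_probs = grade_probs,
              moderate_high_prob = moderate_high_prob,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "oed_generator_config"
  cfg
}

#' Default per-feature generator parameters
#'
#' Pooled prevalences of the twelve features (positive assessments /
#' 327) and the per-event hazard ratios: published point estimates for
#' the six prognostic features, 1 for the others.
#'
#' @return Data frame: `feature`, `prevalence`, `hr_transformation`,
#'   `hr_recurrence`.
#' @export
default_feature_params <- function() {
  pos <- c(basal_cell_hyperplasia = 236, bulbous_rete_pegs = 187,
           dyskeratosis = 110, hyperchromatism = 176,
           irregular_surface_keratin = 196, loss_of_epithelial_cohesion = 98,
           loss_of_stratification = 138, suprabasal_mitoses = 148,
           nuclear_pleomorphism = 118, abrupt_orthokeratosis = 174,
           lymphocytic_band = 112, verrucous_surface = 85)
  hr_t <- c(bulbous_rete_pegs = 8.27, hyperchromatism = 2.96,
            loss_of_epithelial_cohesion = 3.78, loss_of_stratification = 5.35,
            suprabasal_mitoses = 3.06, nuclear_pleomorphism = 3.74)
  hr_r <- c(bulbous_rete_pegs = 2.52, hyperchromatism = 2.90,
            loss_of_epithelial_cohesion = 3.50, loss_of_stratification = 4.50,
            suprabasal_mitoses = 3.17, nuclear_pleomorphism = 3.45)
  f <- oed_features()
  data.frame(
    feature = f,
    prevalence = unname(pos[f] / 327),
    hr_transformation = unname(ifelse(is.na(hr_t[f]), 1, hr_t[f])),
    hr_recurrence = unname(ifelse(is.na(hr_r[f]), 1, hr_r[f])),
    stringsAsFactors = FALSE
  )
}

# P(mild, moderate, severe) by latent six-point count group 0-1 / 2-3 / 4-6;
# chosen to land near the study's 31/44/25 marginal under the default
# prevalences
default_grade_probs <- function() {
  rbind(`0-1` = c(0.75, 0.22, 0.03),
        `2-3` = c(0.29, 0.52, 0.19),
        `4-6` = c(0.05, 0.40, 0.55))
}

validate_generator_config <- function(cfg) {
  chk_prob <- function(x, nm) {
    if (anyNA(x) || any(x < 0 | x > 1)) {
      oed_stop(sprintf("invalid config field '%s': probabilities must lie in [0, 1]", nm))
    }
  }
  if (cfg$n_cases < 1) oed_stop("invalid config field 'n_cases': must be >= 1")
  if (cfg$n_raters < 1) oed_stop("invalid config field 'n_raters': must be >= 1")
  fe <- cfg$features
  need <- c("feature", "prevalence", "hr_transformation", "hr_recurrence")
  if (!all(need %in% names(fe))) {
    oed_stop(sprintf("invalid config field 'features': needs columns %s",
                     paste(need, collapse = ", ")))
  }
  chk_prob(fe$prevalence, "features$prevalence")
  if (any(fe$hr_transformation < 0) || any(fe$hr_recurrence < 0)) {
    oed_stop("invalid config field 'features': hazard ratios must be >= 0")
  }
  chk_prob(cfg$sensitivity, "sensitivity")
  chk_prob(cfg$specificity, "specificity")
  bh <- cfg$baseline_hazard
  if (!all(c("transformation", "recurrence") %in% names(bh))) {
    oed_stop("invalid config field 'baseline_hazard': needs named transformation and recurrence entries")
  }
  if (any(!is.na(bh) & bh < 0)) {
    oed_stop("invalid config field 'baseline_hazard': rates must be >= 0")
  }
  chk_prob(cfg$target_event_rate, "target_event_rate")
  if (cfg$censor_horizon <= 0 || cfg$min_followup <= 0 ||
      cfg$min_followup > cfg$censor_horizon) {
    oed_stop("invalid config field 'censor_horizon'/'min_followup'")
  }
  chk_prob(cfg$early_censor_fraction, "early_censor_fraction")
  if (cfg$severity_sd < 0) oed_stop("invalid config field 'severity_sd': must be >= 0")
  chk_prob(cfg$prop_male, "prop_male")
  chk_prob(cfg$site_probs, "site_probs")
  chk_prob(cfg$treatment_probs, "treatment_probs")
  if (abs(sum(cfg$site_probs) - 1) > 0.02 || abs(sum(cfg$treatment_probs) - 1) > 0.02) {
    oed_stop("invalid config field 'site_probs'/'treatment_probs': must sum to 1")
  }
  gp <- cfg$grade_probs
  if (!is.matrix(gp) || nrow(gp) != 3 || ncol(gp) != 3 ||
      any(gp < 0) || any(abs(rowSums(gp) - 1) > 1e-6)) {
    oed_stop("invalid config field 'grade_probs': 3x3 matrix with rows summing to 1")
  }
  chk_prob(cfg$moderate_high_prob, "moderate_high_prob")
  if (is.na(cfg$seed)) oed_stop("invalid config field 'seed': an integer seed is mandatory")
  invisible(cfg)
}

# solve h0 so that E_features[1 - exp(-h0 * M * t)] = target, where M is the
# product of HR^feature over features with non-null HR (exact enumeration of
# the 2^k combinations of those features)
solve_baseline_hazard <- function(prevalence, hr, target, horizon) {
  if (target == 0) return(0)
  act <- which(abs(hr - 1) > 1e-12)
  if (length(act) > 12) {
    oed_stop("baseline-hazard calibration supports at most 12 non-null hazard ratios")
  }
  if (length(act) == 0) {
    return(-log(1 - target) / horizon)
  }
  p <- prevalence[act]; h <- hr[act]
  combos <- as.matrix(expand.grid(rep(list(0:1), length(act))))
  w <- apply(combos, 1, function(z) prod(ifelse(z == 1, p, 1 - p)))
  M <- apply(combos, 1, function(z) prod(h^z))
  f <- function(h0) sum(w * (1 - exp(-h0 * M * horizon))) - target
  stats::uniroot(f, lower = 1e-12, upper = 10, tol = 1e-12)$root
}

#' Generate a full synthetic multi-rater OED study
#'
#' Draws latent per-case feature vectors, noisy per-rater assessments,
#' clinical covariates, a grade conditional on the latent six-point
#' count, and two independent exponential time-to-event outcomes whose
#' hazard is the baseline rate multiplied by the hazard ratio of every
#' present feature. Fully reproducible from the config's seed.
#'
#' @param config An [generator_config()] object.
#' @param seed Optional seed overriding `config$seed`.
#' @return List with `panel` (a [rating_panel]), `cohort` (validated
#'   cohort data frame), `truth` (latent feature matrix with the
#'   six-point count and per-event hazard rates), and `config` (with
#'   any auto-calibrated baseline hazards filled in).
#' @export
generate <- function(config = generator_config(), seed = NULL) {
  validate_generator_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  set.seed(config$seed)
  n <- config$n_cases
  fe <- config$features
  k <- nrow(fe)
  case_id <- sprintf("case_%04d", seq_len(n))

  # latent features, optionally correlated through a shared severity factor
  if (config$severity_sd > 0) {
    z <- stats::rnorm(n, 0, config$severity_sd)
    lp <- outer(z, rep(1, k))
    in_six <- fe$feature %in% SIX_POINT_FEATURES
    lp[, !in_six] <- 0
    pr <- stats::plogis(sweep(lp, 2, stats::qlogis(fe$prevalence), "+"))
    latent <- matrix(stats::rbinom(n * k, 1, pr), n, k)
  } else {
    latent <- matrix(stats::rbinom(n * k, 1,
                                   rep(fe$prevalence, each = n)), n, k)
  }
  colnames(latent) <- fe$feature

  # noisy rater assessments
  arr <- array(NA_integer_, dim = c(n, config$n_raters, k),
               dimnames = list(case = case_id,
                               rater = paste0("rater_", LETTERS[seq_len(config$n_raters)]),
                               feature = fe$feature))
  for (r in seq_len(config$n_raters)) {
    p1 <- ifelse(latent == 1, config$sensitivity[r], 1 - config$specificity[r])
    arr[, r, ] <- stats::rbinom(n * k, 1, p1)
  }
  panel <- new_rating_panel(case_id, dimnames(arr)$rater, fe$feature, arr)

  # covariates
  age <- pmin(pmax(round(stats::rnorm(n, config$age_mean, config$age_sd)), 18), 95)
  gender <- ifelse(stats::runif(n) < config$prop_male, "male", "female")
  site <- sample(names(config$site_probs), n, replace = TRUE,
                 prob = config$site_probs)
  treatment <- sample(names(config$treatment_probs), n, replace = TRUE,
                      prob = config$treatment_probs)

  # grade conditional on latent six-point count
  count6 <- rowSums(latent[, intersect(fe$feature, SIX_POINT_FEATURES), drop = FALSE])
  grp <- cut(count6, breaks = c(-0.5, 1.5, 3.5, 6.5), labels = FALSE)
  who_grade <- vapply(grp, function(g) {
    sample(COHORT_LEVELS$who_grade, 1, prob = config$grade_probs[g, ])
  }, "")
  binary_grade <- ifelse(
    who_grade == "severe", "high",
    ifelse(who_grade == "mild", "low",
           ifelse(stats::runif(n) < config$moderate_high_prob, "high", "low")))

  # censoring shared by both outcomes (end of follow-up)
  censor <- rep(config$censor_horizon, n)
  early <- stats::runif(n) < config$early_censor_fraction
  censor[early] <- stats::runif(sum(early), config$min_followup,
                                config$censor_horizon)
  if (config$round_times) censor <- ceiling(censor)

  bh <- config$baseline_hazard
  out_events <- list()
  for (ev in c("transformation", "recurrence")) {
    hr <- fe[[paste0("hr_", ev)]]
    h0 <- bh[[ev]]
    if (is.na(h0)) {
      h0 <- solve_baseline_hazard(fe$prevalence, hr,
                                  config$target_event_rate[[ev]],
                                  config$target_horizon)
      bh[[ev]] <- h0
    }
    rate <- h0 * exp(as.vector(latent %*% log(pmax(hr, 1e-300))))
    t_ev <- ifelse(rate > 0, stats::rexp(n, pmax(rate, 1e-300)), Inf)
    if (config$round_times) t_ev <- ceiling(t_ev)
    event <- as.integer(t_ev <= censor)
    time <- pmin(t_ev, censor)
    out_events[[ev]] <- list(event = event, time = time, rate = rate, h0 = h0)
  }
  config$baseline_hazard <- bh

  cohort <- data.frame(
    case_id = case_id, age = age, gender = gender, site = site,
    who_grade = who_grade, binary_grade = binary_grade, treatment = treatment,
    transformation_event = out_events$transformation$event,
    transformation_time = out_events$transformation$time,
    recurrence_event = out_events$recurrence$event,
    recurrence_time = out_events$recurrence$time,
    followup_time = censor,
    stringsAsFactors = FALSE
  )
  cohort <- validate_cohort(cohort, strict = TRUE)

  truth <- data.frame(case_id = case_id, latent, count_six = count6,
                      rate_transformation = out_events$transformation$rate,
                      rate_recurrence = out_events$recurrence$rate,
                      stringsAsFactors = FALSE)
  list(panel = panel, cohort = cohort, truth = truth, config = config)
}

#' Calibration report for a generated study
#'
#' Compares the realised study against the generator's targets:
#' per-feature pooled prevalence (panel vs configured latent
#' prevalence), mean agreement statistics, event fractions by the
#' calibration horizon, and - when enough events occurred - univariate
#' Cox hazard-ratio estimates on the latent features against the
#' configured values. Degenerate calibrations (no events) are flagged.
#'
#' @param sim A [generate()] result.
#' @return List of class `oed_calibration` (plain lists/data frames,
#'   JSON-serialisable).
#' @export
calibration_report <- function(sim) {
  cfg <- sim$config
  tab <- agreement_table(sim$panel)
  prev <- data.frame(
    feature = cfg$features$feature,
    target = cfg$features$prevalence,
    realised = tab$prevalence[match(cfg$features$feature, tab$feature)],
    stringsAsFactors = FALSE)
  prev$abs_diff <- abs(prev$realised - prev$target)

  horizon <- cfg$target_horizon
  events <- lapply(c("transformation", "recurrence"), function(ev) {
    st <- sim$cohort[[paste0(ev, "_event")]]
    tm <- sim$cohort[[paste0(ev, "_time")]]
    list(event = ev,
         target_rate = unname(cfg$target_event_rate[[ev]]),
         realised_rate_by_horizon = mean(st == 1 & tm <= horizon),
         realised_rate_any_time = mean(st == 1),
         n_events = sum(st),
         degenerate = sum(st) == 0)
  })
  names(events) <- c("transformation", "recurrence")

  # the configured HRs are conditional (multiplicative per feature), so
  # recovery uses one joint Cox fit on the latent features, not univariate
  # fits, which marginalisation would attenuate
  hr_fits <- NULL
  feats6 <- intersect(cfg$features$feature, SIX_POINT_FEATURES)
  if (all(vapply(events, function(e) e$n_events, 0) >= 5) && length(feats6) > 0) {
    cov <- sim$truth[, c("case_id", feats6), drop = FALSE]
    rows <- lapply(c("transformation", "recurrence"), function(ev) {
      fit <- tryCatch(cox_fit(sim$cohort, ev, cov), error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      tb <- fit$table
      data.frame(feature = tb$term, event = ev,
                 target_hr = cfg$features[[paste0("hr_", ev)]][
                   match(tb$term, cfg$features$feature)],
                 hr = tb$hr, lower = tb$lower, upper = tb$upper,
                 stringsAsFactors = FALSE)
    })
    hr_fits <- do.call(rbind, rows)
  }

  structure(list(
    n_cases = cfg$n_cases,
    seed = cfg$seed,
    baseline_hazard = as.list(cfg$baseline_hazard),
    prevalence = prev,
    mean_kappa = mean(tab$kappa, na.rm = TRUE),
    mean_ac1 = mean(tab$ac1, na.rm = TRUE),
    events = events,
    degenerate = any(vapply(events, function(e) e$degenerate, TRUE)),
    hr_recovery = hr_fits
  ), class = "oed_calibration")
}

#' @export
print.oed_calibration <- function(x, ...) {
  cat(sprintf("calibration: n = %d, seed = %d\n", x$n_cases, x$seed))
  cat(sprintf("  mean |prevalence error| = %.3f; mean kappa = %.2f, mean AC1 = %.2f\n",
              mean(x$prevalence$abs_diff), x$mean_kappa, x$mean_ac1))
  for (e in x$events) {
    cat(sprintf("  %s: realised %.1f%% by horizon (target %.1f%%), %d events%s\n",
                e$event, 100 * e$realised_rate_by_horizon, 100 * e$target_rate,
                e$n_events, if (e$degenerate) " [DEGENERATE]" else ""))
  }
  invisible(x)
}
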