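#' AUROC of a numeric predictor for a binary outcome
#'
#' Computes the area under the ROC curve via the midrank (Mann-Whitney)
#' statistic, so tied predictor values count 1/2, together with the full
#' ROC point set over the predictor's distinct values. The outcome is
#' the binary "event at any time during follow-up".
#'
#' @param score Numeric predictor, one value per case.
#' @param event Binary 0/1 outcome, same length.
#' @param label Optional predictor label carried into reports.
#' @param case_id Optional case identifiers (enables paired AUC
#'   comparison checks).
#' @return Object of class `oed_roc`: `auc`, `n_pos`, `n_neg`,
#'   `points` (data frame `threshold`, `sensitivity`, `fpr`), plus the
#'   raw `score`/`event` vectors.
#' @examples
#' auroc(c(0, 1, 2, 3), c(0, 0, 1, 1))$auc   # 1
#' auroc(c(0, 1, 1, 2), c(0, 1, 0, 1))$auc   # 0.875
#' @export
auroc <- function(score, event, label = "score", case_id = NULL) {
  if (length(score) != length(event)) oed_stop("score and event lengths differ")
  if (anyNA(score) || anyNA(event)) oed_stop("score/event must not contain NA")
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) oed_stop("event must be 0/1")
  n_pos <- sum(event == 1)
  n_neg <- sum(event == 0)
  if (n_pos == 0 || n_neg == 0) {
    oed_stop("degenerate outcome: need at least one event and one non-event")
  }
  r <- rank(score, ties.method = "average")
  auc <- (sum(r[event == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- sort(unique(score), decreasing = TRUE)
  pts <- data.frame(
    threshold = c(Inf, thr),
    sensitivity = c(0, vapply(thr, function(t) mean(score[event == 1] >= t), 0)),
    fpr = c(0, vapply(thr, function(t) mean(score[event == 0] >= t), 0))
  )
  structure(list(label = label, auc = auc, n_pos = n_pos, n_neg = n_neg,
                 points = pts, score = score, event = event,
                 case_id = case_id),
            class = "oed_roc")
}

#' @export
print.oed_roc <- function(x, ...) {
  cat(sprintf("ROC '%s': AUROC = %.3f (%d events / %d non-events)\n",
              x$label, x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUROCs of two predictors measured on the same cases
#' with the same outcomes, using the DeLong placement-value variance
#' of the paired difference; two-sided p-value. Identical predictors
#' give a difference of 0 and p = 1 exactly.
#'
#' @param a,b [auroc()] results on the identical case set.
#' @return List: `auc_a`, `auc_b`, `diff`, `se`, `z`, `p`.
#' @export
compare_auroc <- function(a, b) {
  stopifnot(inherits(a, "oed_roc"), inherits(b, "oed_roc"))
  if (length(a$event) != length(b$event) || any(a$event != b$event)) {
    oed_stop("predictors were not evaluated on identical cases/outcomes")
  }
  if (!is.null(a$case_id) && !is.null(b$case_id) &&
      !identical(a$case_id, b$case_id)) {
    oed_stop("case identifiers differ between the two ROC results")
  }
  pos <- a$event == 1
  xa <- a$score[pos]; ya <- a$score[!pos]
  xb <- b$score[pos]; yb <- b$score[!pos]
  m <- length(xa); n <- length(ya)

  psi <- function(x, y) {
    # m x n matrix of Mann-Whitney kernel values
    outer(x, y, function(u, v) (u > v) + 0.5 * (u == v))
  }
  Ka <- psi(xa, ya); Kb <- psi(xb, yb)
  v10 <- cbind(rowMeans(Ka), rowMeans(Kb))   # placements over positives
  v01 <- cbind(colMeans(Ka), colMeans(Kb))   # placements over negatives
  auc <- c(mean(v10[, 1]), mean(v10[, 2]))
  s10 <- stats::cov(v10)
  s01 <- stats::cov(v01)
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- auc[1] - auc[2]
  if (var_diff <= 0 || !is.finite(var_diff)) {
    if (abs(d) < 1e-12) {
      z <- 0; p <- 1
    } else {
      warning("zero variance for a non-zero AUC difference; p reported as 0")
      z <- sign(d) * Inf; p <- 0
    }
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = auc[1], auc_b = auc[2], diff = d,
       se = sqrt(max(var_diff, 0)), z = z, p = p)
}

#' Event incidence by feature presence
#'
#' For each feature, counts and percentages of cases with each event
#' among feature-positive and feature-negative cases (event at any time
#' during follow-up). A presence arm with no cases gets `NA`
#' percentages rather than 0.
#'
#' @param cohort Validated cohort data frame.
#' @param profiles An `oed_profile` data frame aligned to the cohort.
#' @param events Events to tabulate (default both).
#' @return Data frame: `feature`, `event`, `n_positive`, `events_positive`,
#'   `pct_positive`, `n_negative`, `events_negative`, `pct_negative`.
#' @export
incidence_table <- function(cohort, profiles,
                            events = c("transformation", "recurrence")) {
  idx <- match(cohort$case_id, profiles$case_id)
  if (any(is.na(idx))) oed_stop("profiles missing for some cohort cases")
  profiles <- profiles[idx, , drop = FALSE]
  feats <- setdiff(names(profiles), c("case_id", "source"))
  rows <- list()
  for (ev in events) {
    status <- cohort[[paste0(ev, "_event")]]
    for (f in feats) {
      pres <- profiles[[f]] == 1
      np <- sum(pres); nn <- sum(!pres)
      ep <- sum(status[pres]); en <- sum(status[!pres])
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, event = ev,
        n_positive = np, events_positive = ep,
        pct_positive = if (np > 0) 100 * ep / np else NA_real_,
        n_negative = nn, events_negative = en,
        pct_negative = if (nn > 0) 100 * en / nn else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# numeric encodings for model covariates: WHO grade ordinal 1-3,
# binary grade 0/1, gender 0/1 (male = 1), age in years
encode_covariates <- function(cohort, covariates) {
  allowed <- c("age", "gender", "who_grade", "binary_grade")
  bad <- setdiff(covariates, allowed)
  if (length(bad) > 0) {
    oed_stop(sprintf("unsupported covariate(s): %s (allowed: %s)",
                     paste(bad, collapse = ", "), paste(allowed, collapse = ", ")))
  }
  out <- data.frame(row.names = seq_len(nrow(cohort)))
  if ("age" %in% covariates) out$age <- cohort$age
  if ("gender" %in% covariates) out$gender <- as.integer(cohort$gender == "male")
  if ("who_grade" %in% covariates) {
    out$who_grade <- match(cohort$who_grade, COHORT_LEVELS$who_grade)
  }
  if ("binary_grade" %in% covariates) {
    out$binary_grade <- as.integer(cohort$binary_grade == "high")
  }
  out
}

#' AUROC of a covariate-augmented score model
#'
#' Fits an in-sample logistic model of the binary outcome on the score
#' plus the requested clinical covariates, and reports the AUROC of the
#' fitted probabilities (no held-out split). If the logistic fit shows
#' separation, a ridge-penalised fit (small L2 penalty) is used instead
#' and the result is flagged.
#'
#' @param cohort Validated cohort data frame.
#' @param score Numeric score per case, aligned with `cohort` rows.
#' @param covariates Subset of `c("age", "gender", "who_grade",
#'   "binary_grade")`; empty for score-only.
#' @param event `"transformation"` or `"recurrence"`.
#' @param label Predictor label for the result.
#' @return An [auroc()] result with attribute `"penalized"` (logical)
#'   and `"model"` (the fitted object).
#' @export
augmented_model_auroc <- function(cohort, score, covariates = character(0),
                                  event = c("transformation", "recurrence"),
                                  label = NULL) {
  event <- match.arg(event)
  y <- cohort[[paste0(event, "_event")]]
  X <- encode_covariates(cohort, covariates)
  X <- cbind(data.frame(score = score), X)
  if (anyNA(X)) oed_stop("missing covariate values")
  label <- label %||% paste(c("score", covariates), collapse = " + ")

  dat <- cbind(data.frame(.y = y), X)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!separated && any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)) {
    separated <- TRUE
  }
  if (separated) {
    warning(sprintf("separation detected for model '%s'; using ridge-penalised fit", label))
    xm <- as.matrix(X)
    fit <- glmnet::glmnet(xm, y, family = "binomial", alpha = 0,
                          lambda = 1e-2, standardize = TRUE)
    pred <- as.numeric(stats::predict(fit, newx = xm, type = "link"))
  } else {
    pred <- stats::predict(fit, type = "link")
  }
  res <- auroc(as.numeric(pred), y, label = label, case_id = cohort$case_id)
  attr(res, "penalized") <- separated
  attr(res, "model") <- fit
  res
}

#' Per-rater and consensus model performance
#'
#' Recomputes the prognostic scores from each single rater's profile and
#' from the consensus profile, and tabulates the AUROC for each model
#' and event: how the models behave in single-assessor use versus
#' consensus reporting.
#'
#' @param panel A [rating_panel].
#' @param cohort Validated cohort data frame covering the panel's cases.
#' @param models Models to evaluate (default both).
#' @param events Events to evaluate (default both).
#' @param min_agree Consensus threshold passed to [consensus_profile()].
#' @return Data frame: `model`, `event`, `source`, `auc`.
#' @export
per_rater_evaluation <- function(panel, cohort,
                                 models = c("two_point", "six_point"),
                                 events = c("transformation", "recurrence"),
                                 min_agree = NULL) {
  sources <- c(lapply(panel$raters, function(r) rater_profile(panel, r)),
               list(consensus_profile(panel, min_agree = min_agree)))
  rows <- list()
  for (model in models) {
    for (ev in events) {
      y <- cohort[[paste0(ev, "_event")]]
      for (prof in sources) {
        prof_o <- prof[match(cohort$case_id, prof$case_id), , drop = FALSE]
        sc <- score_cohort(prof_o, model = model)
        sc <- sc[match(cohort$case_id, sc$case_id), ]
        rows[[length(rows) + 1]] <- data.frame(
          model = model, event = ev, source = prof$source[1],
          auc = auroc(sc$score, y)$auc, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
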