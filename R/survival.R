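#' Kaplan-Meier curves by stratum
#'
#' Product-limit estimator per stratum with Greenwood variance and
#' pointwise 95% confidence intervals on the complementary log-log
#' scale (back-transformed), as produced by standard survival software.
#' Strata with zero events are returned flagged, with the curve
#' constant at 1 and intervals undefined.
#'
#' @param cohort Validated cohort data frame (see [validate_cohort()]).
#' @param event `"transformation"` or `"recurrence"`.
#' @param strata Optional stratum label per case: a data frame with
#'   columns `case_id` and `stratum`, or a vector named by `case_id`,
#'   or `NULL` for a single overall curve. Labels must cover all cases.
#' @return Object of class `oed_km`: list with `event`, `curves` (one
#'   per stratum: `stratum`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, `std_err`, `lower`, `upper`, `n`, `events_total`,
#'   `zero_events` flag).
#' @seealso [km_risk()] for 1 - S(t) at chosen horizons.
#' @export
km_fit <- function(cohort, event = c("transformation", "recurrence"),
                   strata = NULL) {
  event <- match.arg(event)
  time <- cohort[[paste0(event, "_time")]]
  status <- cohort[[paste0(event, "_event")]]
  # event-free cases are censored at end of follow-up
  time[status == 0] <- cohort$followup_time[status == 0]
  if (any(time <= 0)) oed_stop("all event/censoring times must be > 0")

  lab <- resolve_strata(cohort, strata)
  df <- data.frame(time = time, status = status, stratum = lab)
  fit <- survival::survfit(survival::Surv(time, status) ~ stratum, data = df,
                           conf.type = "log-log", conf.int = 0.95)
  sm <- summary(fit, censored = TRUE)
  if (is.null(sm$strata)) {
    groups <- factor(rep(levels(factor(lab))[1], length(sm$time)))
  } else {
    groups <- factor(sub("^stratum=", "", as.character(sm$strata)),
                     levels = sub("^stratum=", "", levels(sm$strata)))
  }
  curves <- lapply(levels(groups), function(g) {
    i <- groups == g
    ev_total <- sum(sm$n.event[i])
    list(stratum = g,
         time = sm$time[i],
         n_risk = sm$n.risk[i],
         n_event = sm$n.event[i],
         n_censor = sm$n.censor[i],
         surv = sm$surv[i],
         std_err = sm$std.err[i],
         lower = sm$lower[i],
         upper = sm$upper[i],
         n = sum(df$stratum == g),
         events_total = ev_total,
         zero_events = ev_total == 0)
  })
  names(curves) <- levels(groups)
  for (cv in curves) {
    if (cv$zero_events) {
      warning(sprintf("stratum '%s' has zero events: survival constant at 1, intervals undefined", cv$stratum))
    }
  }
  structure(list(event = event, curves = curves), class = "oed_km")
}

resolve_strata <- function(cohort, strata) {
  if (is.null(strata)) return(rep("all", nrow(cohort)))
  if (is.data.frame(strata)) {
    strata <- stats::setNames(strata$stratum, strata$case_id)
  }
  if (is.null(names(strata))) {
    if (length(strata) != nrow(cohort)) {
      oed_stop("unnamed strata must have one label per cohort row")
    }
    return(as.character(strata))
  }
  miss <- setdiff(cohort$case_id, names(strata))
  if (length(miss) > 0) {
    oed_stop(sprintf("strata labels missing for case(s): %s",
                     paste(utils::head(miss, 5), collapse = ", ")))
  }
  as.character(strata[cohort$case_id])
}

#' Event risk at given horizons from a Kaplan-Meier fit
#'
#' Reports `1 - S(t)` with the interval obtained by transforming the
#' survival interval (lower risk = 1 - upper survival bound).
#'
#' @param km An [km_fit()] result.
#' @param times Horizons in months (default 24 and 60, i.e. 2 and 5
#'   years).
#' @return Data frame: `stratum`, `time`, `risk`, `lower`, `upper`.
#' @export
km_risk <- function(km, times = c(24, 60)) {
  stopifnot(inherits(km, "oed_km"))
  rows <- lapply(km$curves, function(cv) {
    do.call(rbind, lapply(times, function(t0) {
      i <- which(cv$time <= t0)
      if (length(i) == 0) {
        s <- 1; lo <- NA_real_; hi <- NA_real_
      } else {
        j <- max(i)
        s <- cv$surv[j]; lo <- cv$lower[j]; hi <- cv$upper[j]
      }
      data.frame(stratum = cv$stratum, time = t0, risk = 1 - s,
                 lower = 1 - ifelse(is.na(hi), NA, hi),
                 upper = 1 - ifelse(is.na(lo), NA, lo),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cox proportional-hazards fit with Efron tie correction
#'
#' Fits a Cox model for the chosen event on the supplied covariate
#' columns, handling tied event times with Efron's correction. Reports
#' hazard ratios with Wald 95% intervals `exp(beta +/- 1.96 se)` and
#' two-sided Wald p-values.
#'
#' @param cohort Validated cohort data frame.
#' @param event `"transformation"` or `"recurrence"`.
#' @param covariates Data frame with `case_id` plus numeric covariate
#'   columns, aligned to the cohort by `case_id`.
#' @return Object of class `oed_coxfit`: data frame `table`
#'   (term, coef, hr, se, lower, upper, p) plus `loglik`, `iter`,
#'   `flags` (e.g. suspected monotone likelihood / infinite estimate).
#' @export
cox_fit <- function(cohort, event = c("transformation", "recurrence"),
                    covariates) {
  event <- match.arg(event)
  if (!("case_id" %in% names(covariates))) {
    oed_stop("covariates must contain a case_id column")
  }
  idx <- match(cohort$case_id, covariates$case_id)
  if (any(is.na(idx))) {
    oed_stop(sprintf("covariates missing for case(s): %s",
                     paste(utils::head(cohort$case_id[is.na(idx)], 5), collapse = ", ")))
  }
  X <- covariates[idx, setdiff(names(covariates), "case_id"), drop = FALSE]
  if (ncol(X) == 0) oed_stop("no covariate columns supplied")
  for (cn in names(X)) {
    v <- X[[cn]]
    if (!is.numeric(v)) oed_stop(sprintf("covariate '%s' must be numeric", cn))
    if (length(unique(v)) < 2) {
      oed_stop(sprintf("covariate '%s' is constant: non-identifiable", cn),
               class = "oedprog_nonidentifiable")
    }
  }
  status <- cohort[[paste0(event, "_event")]]
  time <- cohort[[paste0(event, "_time")]]
  time[status == 0] <- cohort$followup_time[status == 0]
  if (sum(status) == 0) oed_stop("no events: Cox model is not estimable")

  dat <- cbind(data.frame(.time = time, .status = status), X)
  flags <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .status) ~ ., data = dat,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w), ignore.case = TRUE)) {
        flags <<- c(flags, paste0("possible monotone likelihood: ",
                                  conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- beta / se
  tab <- data.frame(
    term = names(beta),
    coef = unname(beta),
    hr = exp(unname(beta)),
    se = unname(se),
    lower = exp(unname(beta) - 1.96 * unname(se)),
    upper = exp(unname(beta) + 1.96 * unname(se)),
    p = 2 * stats::pnorm(-abs(unname(z))),
    stringsAsFactors = FALSE
  )
  structure(list(event = event, table = tab,
                 loglik = fit$loglik[length(fit$loglik)],
                 iter = fit$iter, n = nrow(dat), n_events = sum(status),
                 flags = flags),
            class = "oed_coxfit")
}

#' @export
print.oed_coxfit <- function(x, ...) {
  cat(sprintf("Cox PH (Efron ties), event = %s, n = %d, events = %d\n",
              x$event, x$n, x$n_events))
  tb <- x$table
  tb$hr <- sprintf("%.2f (%.2f, %.2f)", tb$hr, tb$lower, tb$upper)
  print(tb[, c("term", "hr", "p")], row.names = FALSE)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Univariate Cox fits for every feature
#'
#' One single-covariate Cox model (Efron ties) per feature per event,
#' mirroring a per-feature hazard-ratio table. Features that are
#' constant in the profiles are flagged non-identifiable and reported
#' with `NA` estimates rather than aborting the table.
#'
#' @param cohort Validated cohort data frame.
#' @param profiles An `oed_profile` data frame aligned to the cohort.
#' @param events Events to fit (default both).
#' @return Data frame: `feature`, `event`, `hr`, `lower`, `upper`, `p`,
#'   `significant` (p < 0.05), `flag`.
#' @export
univariate_feature_cox <- function(cohort, profiles,
                                   events = c("transformation", "recurrence")) {
  feats <- setdiff(names(profiles), c("case_id", "source"))
  rows <- list()
  for (ev in events) {
    for (f in feats) {
      cov <- profiles[, c("case_id", f)]
      res <- tryCatch(cox_fit(cohort, ev, cov), error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1]] <- data.frame(
          feature = f, event = ev, hr = NA_real_, lower = NA_real_,
          upper = NA_real_, p = NA_real_, significant = NA,
          flag = conditionMessage(res), stringsAsFactors = FALSE)
      } else {
        tb <- res$table
        rows[[length(rows) + 1]] <- data.frame(
          feature = f, event = ev, hr = tb$hr, lower = tb$lower,
          upper = tb$upper, p = tb$p, significant = tb$p < 0.05,
          flag = if (length(res$flags)) paste(res$flags, collapse = "; ") else "",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
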