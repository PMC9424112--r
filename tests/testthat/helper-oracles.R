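# Independent brute-force oracles and fixture builders. These stay
# deliberately naive (explicit enumeration) so they cannot share a bug
# with the vectorised implementations they check.

# observed pairwise agreement by explicit enumeration of all rater pairs
oracle_pa <- function(panel, feature) {
  m <- panel$assessments[, , match(feature, panel$features), drop = FALSE]
  dim(m) <- dim(m)[1:2]
  agree <- 0; total <- 0
  for (i in seq_len(nrow(m))) {
    obs <- which(!is.na(m[i, ]))
    if (length(obs) < 2) next
    for (a in seq_along(obs)[-length(obs)]) {
      for (b in (a + 1):length(obs)) {
        total <- total + 1
        if (m[i, obs[a]] == m[i, obs[b]]) agree <- agree + 1
      }
    }
  }
  agree / total
}

# AUROC by explicit comparison of every (event, non-event) pair, ties 1/2
oracle_auc <- function(score, event) {
  pos <- score[event == 1]
  neg <- score[event == 0]
  s <- 0
  for (x in pos) for (y in neg) {
    s <- s + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# exact Cox partial log-likelihood for tie-free data (equals Efron and
# Breslow when no times coincide); maximised by optimise()
oracle_cox_beta <- function(time, status, x) {
  stopifnot(!any(duplicated(time[status == 1])))
  nll <- function(beta) {
    ll <- 0
    for (i in which(status == 1)) {
      risk <- time >= time[i]
      ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
    }
    -ll
  }
  stats::optimise(nll, c(-10, 10), tol = 1e-10)$minimum
}

# random complete binary panel
random_panel <- function(n, r, f = 1, p = 0.5) {
  arr <- array(stats::rbinom(n * r * f, 1, p), dim = c(n, r, f))
  panel_from_matrix(arr, features = paste0("f", seq_len(f)))
}

# minimal valid cohort around given outcome vectors
make_cohort <- function(time, status, event = "transformation",
                        followup = NULL, x = NULL) {
  n <- length(time)
  followup <- followup %||% pmax(time, 60)
  df <- data.frame(
    case_id = sprintf("c%03d", seq_len(n)),
    age = 60, gender = "male", site = "tongue", who_grade = "mild",
    binary_grade = "low", treatment = "excised",
    transformation_event = 0L, transformation_time = followup,
    recurrence_event = 0L, recurrence_time = followup,
    followup_time = followup, stringsAsFactors = FALSE)
  df[[paste0(event, "_event")]] <- as.integer(status)
  df[[paste0(event, "_time")]] <- time
  df$followup_time <- pmax(df$followup_time, time)
  validate_cohort(df, strict = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full profile with all 12 features set to 0 except those named
profile_with <- function(case_id = "c1", present = character(0)) {
  out <- data.frame(case_id = case_id, source = "consensus",
                    stringsAsFactors = FALSE)
  for (f in oed_features()) out[[f]] <- as.integer(f %in% present)
  class(out) <- c("oed_profile", "data.frame")
  out
}
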