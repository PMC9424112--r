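#' Inter-rater agreement statistics for one feature
#'
#' For binary assessments by `r` raters on `n` cases, the observed
#' pairwise agreement is
#' \deqn{P_a = \sum_i a_i / \sum_i m_i(m_i-1)/2,}
#' where for case \eqn{i} with \eqn{m_i} non-missing assessments of
#' which \eqn{k_i} are positive, \eqn{a_i = \binom{k_i}{2} +
#' \binom{m_i-k_i}{2}} is the number of agreeing rater pairs (pairwise
#' deletion, each case weighted by its own pair count). With pooled
#' positive fraction \eqn{\pi}, chance agreement is
#' \eqn{\pi^2 + (1-\pi)^2} for the Fleiss-type kappa and
#' \eqn{2\pi(1-\pi)} for Gwet's AC1; each coefficient is
#' \eqn{(P_a - P_e)/(1 - P_e)}.
#'
#' `observed_agreement()` returns only \eqn{P_a} and the complete
#' (all-rater) agreement; [gwet_ac1()] and [multirater_kappa()] return
#' the full summary row.
#'
#' @param panel A [rating_panel].
#' @param feature Canonical feature identifier present in the panel.
#' @return For `observed_agreement()`: list with `pa`,
#'   `complete_agreement_count`, `complete_agreement_fraction`,
#'   `n_included`.
#' @export
observed_agreement <- function(panel, feature) {
  s <- agreement_summary(panel, feature)
  list(pa = s$pa,
       complete_agreement_count = s$complete_agreement_count,
       complete_agreement_fraction = s$complete_agreement_fraction,
       n_included = s$n_cases)
}

# one-row agreement summary for a feature; shared engine
agreement_summary <- function(panel, feature) {
  stopifnot(inherits(panel, "rating_panel"))
  if (!feature %in% panel$features) {
    oed_stop(sprintf("feature '%s' not in panel (has: %s)", feature,
                     paste(panel$features, collapse = ", ")))
  }
  if (length(panel$raters) < 2) {
    oed_stop("agreement requires at least 2 raters")
  }
  m <- panel$assessments[, , match(feature, panel$features), drop = FALSE]
  dim(m) <- dim(m)[1:2]
  k1 <- rowSums(m == 1, na.rm = TRUE)
  k0 <- rowSums(m == 0, na.rm = TRUE)
  mm <- k1 + k0
  keep <- mm >= 2
  if (!any(keep)) oed_stop(sprintf("no case has >= 2 assessments for '%s'", feature))
  k1 <- k1[keep]; k0 <- k0[keep]; mm <- mm[keep]

  pairs <- mm * (mm - 1) / 2
  agree <- choose(k1, 2) + choose(k0, 2)
  pa <- sum(agree) / sum(pairs)
  complete <- (k1 == mm) | (k0 == mm)

  n_pos <- sum(k1)
  n_assess <- sum(mm)
  pi_hat <- n_pos / n_assess
  pe_kappa <- pi_hat^2 + (1 - pi_hat)^2
  pe_ac1 <- 2 * pi_hat * (1 - pi_hat)
  if (pe_kappa >= 1 - 1e-12) {
    warning(sprintf(
      "kappa undefined for '%s': pooled prevalence is %g so chance agreement is 1",
      feature, pi_hat))
    kappa <- NaN
  } else {
    kappa <- (pa - pe_kappa) / (1 - pe_kappa)
  }
  ac1 <- (pa - pe_ac1) / (1 - pe_ac1)

  data.frame(
    feature = feature,
    n_cases = sum(keep),
    n_raters = length(panel$raters),
    positive_assessments = n_pos,
    n_assessments = n_assess,
    prevalence = pi_hat,
    complete_agreement_count = sum(complete),
    complete_agreement_fraction = mean(complete),
    pa = pa,
    pe_kappa = pe_kappa,
    pe_ac1 = pe_ac1,
    kappa = kappa,
    ac1 = ac1,
    stringsAsFactors = FALSE
  )
}

#' @rdname observed_agreement
#' @export
gwet_ac1 <- function(panel, feature) {
  agreement_summary(panel, feature)
}

#' @rdname observed_agreement
#' @param method `"fleiss"` (default): chance agreement from pooled
#'   marginals, \eqn{\pi^2+(1-\pi)^2}. `"pairwise_cohen"`: mean of
#'   two-rater Cohen's kappas using rater-specific marginals, offered
#'   for comparison.
#' @export
multirater_kappa <- function(panel, feature, method = c("fleiss", "pairwise_cohen")) {
  method <- match.arg(method)
  s <- agreement_summary(panel, feature)
  if (method == "pairwise_cohen") {
    s$kappa <- pairwise_cohen_kappa(panel, feature)
  }
  s
}

# mean Cohen's kappa over rater pairs, complete cases per pair
pairwise_cohen_kappa <- function(panel, feature) {
  m <- panel$assessments[, , match(feature, panel$features), drop = FALSE]
  dim(m) <- dim(m)[1:2]
  r <- ncol(m)
  ks <- c()
  for (i in seq_len(r - 1)) for (j in (i + 1):r) {
    ok <- !is.na(m[, i]) & !is.na(m[, j])
    a <- m[ok, i]; b <- m[ok, j]
    if (length(a) == 0) next
    po <- mean(a == b)
    pe <- mean(a) * mean(b) + mean(1 - a) * mean(1 - b)
    ks <- c(ks, if (pe >= 1 - 1e-12) NaN else (po - pe) / (1 - pe))
  }
  mean(ks)
}

#' Per-feature agreement table
#'
#' One [agreement_summary] row per feature, ordered as in the panel
#' (canonical vocabulary first).
#'
#' @param panel A [rating_panel].
#' @return Data frame with one row per feature (columns as in
#'   [gwet_ac1()]).
#' @export
agreement_table <- function(panel) {
  stopifnot(inherits(panel, "rating_panel"))
  if (length(panel$features) == 0) oed_stop("panel has no features")
  out <- do.call(rbind, lapply(panel$features, function(f) agreement_summary(panel, f)))
  rownames(out) <- NULL
  out
}

#' Format an agreement table for reporting
#'
#' Rounds coefficients to 2 decimal places (half away from zero) and
#' renders prevalence/complete agreement as percentages, matching the
#' usual presentation of observer-agreement tables.
#'
#' @param tab Output of [agreement_table()].
#' @return Data frame with display columns.
#' @export
format_agreement_table <- function(tab) {
  data.frame(
    feature = feature_label(tab$feature),
    prevalence = sprintf("%d (%d%%)", tab$positive_assessments,
                         round(100 * tab$prevalence)),
    complete_agreement = sprintf("%d (%d%%)", tab$complete_agreement_count,
                                 round(100 * tab$complete_agreement_fraction)),
    kappa = round_half_up(tab$kappa, 2),
    ac1 = round_half_up(tab$ac1, 2),
    stringsAsFactors = FALSE
  )
}

#' Construct a three-rater panel matching printed agreement marginals
#'
#' For three binary raters, the pair (positive assessments out of
#' \eqn{3n}, complete-agreement cases out of \eqn{n}) fully determines
#' every agreement statistic: any non-unanimous case must be a 2-1
#' split. This helper builds one concrete panel with the requested
#' marginals, which is useful for reproducing published agreement
#' coefficients from their printed summary counts. The panel is
#' synthetic: individual case patterns are arbitrary up to the
#' marginals.
#'
#' @param n_cases Number of cases (default 109).
#' @param positives Total positive assessments across the `3 * n_cases`
#'   assessments.
#' @param unanimous Number of cases on which all three raters agree.
#' @param feature Feature identifier for the constructed panel.
#' @return A [rating_panel] with 3 raters and one feature.
#' @export
panel_from_marginals <- function(n_cases = 109, positives, unanimous,
                                 feature = "feature_1") {
  non_unan <- n_cases - unanimous
  if (non_unan < 0) oed_stop("unanimous exceeds n_cases")
  # split counts: u1 all-(1,1,1) cases, a cases (1,1,0), b cases (1,0,0)
  # 3*u1 + 2*a + b = positives, a + b = non_unan  =>  u1 = (positives - non_unan - a)/3
  found <- NULL
  for (a in 0:non_unan) {
    u1 <- (positives - non_unan - a) / 3
    if (u1 == floor(u1) && u1 >= 0 && u1 <= unanimous) {
      found <- c(a = a, u1 = u1)
      break
    }
  }
  if (is.null(found)) {
    oed_stop(sprintf(
      "no three-rater panel has %d positives of %d and %d unanimous of %d cases",
      positives, 3 * n_cases, unanimous, n_cases))
  }
  a <- found["a"]; u1 <- found["u1"]
  b <- non_unan - a
  u0 <- unanimous - u1
  rows <- rbind(
    matrix(rep(c(1, 1, 1), u1), ncol = 3, byrow = TRUE),
    matrix(rep(c(0, 0, 0), u0), ncol = 3, byrow = TRUE),
    matrix(rep(c(1, 1, 0), a), ncol = 3, byrow = TRUE),
    matrix(rep(c(1, 0, 0), b), ncol = 3, byrow = TRUE)
  )
  panel_from_matrix(rows, features = feature)
}
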