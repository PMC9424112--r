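#' Six-point feature-count prognostic score
#'
#' Allocates one point for the presence of each of the six features most
#' strongly associated with transformation and recurrence
#' ([SIX_POINT_FEATURES]); each feature carries equal weight. The
#' canonical risk strata are 0-1, 2-3 and 4-6 points; the cut-points are
#' configurable for threshold exploration, but the defaults are the
#' model's definition.
#'
#' @param profiles An `oed_profile` data frame ([consensus_profile()] or
#'   [rater_profile()]).
#' @param breaks Two increasing upper bounds for the first two strata
#'   (default `c(1, 3)` giving 0-1 / 2-3 / 4-6).
#' @return Data frame of class `score_result`: `case_id`, `model`,
#'   `score`, `stratum` (ordered factor), `source`.
#' @export
six_point_score <- function(profiles, breaks = c(1, 3)) {
  feats <- check_score_features(profiles, SIX_POINT_FEATURES)
  score <- as.integer(rowSums(profiles[, feats, drop = FALSE]))
  labs <- c(paste0("0-", breaks[1]),
            paste0(breaks[1] + 1, "-", breaks[2]),
            paste0(breaks[2] + 1, "-", length(feats)))
  stratum <- cut(score, breaks = c(-0.5, breaks + 0.5, length(feats) + 0.5),
                 labels = labs, ordered_result = TRUE)
  new_score_result(profiles, "six_point", score, stratum)
}

#' Two-point reduced prognostic score
#'
#' Counts the two features with the best inter-rater agreement among the
#' prognostic set: loss of epithelial cohesion and bulbous/drop-shaped
#' rete pegs. The stratum is the presence pattern (neither /
#' cohesion_only / bulbous_only / both) so that single-feature risk
#' groups stay distinguishable.
#'
#' @inheritParams six_point_score
#' @return A `score_result` data frame (`score` 0-2, `stratum` the
#'   presence category).
#' @export
two_point_score <- function(profiles) {
  feats <- check_score_features(profiles, TWO_POINT_FEATURES)
  coh <- profiles[["loss_of_epithelial_cohesion"]]
  bul <- profiles[["bulbous_rete_pegs"]]
  score <- as.integer(coh + bul)
  stratum <- factor(ifelse(coh == 1 & bul == 1, "both",
                    ifelse(coh == 1, "cohesion_only",
                    ifelse(bul == 1, "bulbous_only", "neither"))),
                    levels = c("neither", "cohesion_only", "bulbous_only", "both"))
  new_score_result(profiles, "two_point", score, stratum)
}

check_score_features <- function(profiles, feats) {
  missing <- setdiff(feats, names(profiles))
  if (length(missing) > 0) {
    oed_stop(sprintf("profile is missing scoring feature(s): %s",
                     paste(missing, collapse = ", ")))
  }
  feats
}

new_score_result <- function(profiles, model, score, stratum) {
  out <- data.frame(case_id = profiles$case_id, model = model,
                    score = score, stratum = stratum,
                    source = profiles$source, stringsAsFactors = FALSE)
  class(out) <- c("score_result", "data.frame")
  out
}

#' Score a cohort of profiles
#'
#' Vectorised scoring with stable case ordering and a stratum-count
#' summary attached as attribute `"stratum_counts"`.
#'
#' @param profiles An `oed_profile` data frame; duplicate `case_id`s are
#'   an error.
#' @param model `"six_point"` or `"two_point"`.
#' @param ... Passed to the model's scoring function.
#' @return A `score_result` data frame ordered by `case_id`.
#' @export
score_cohort <- function(profiles, model = c("six_point", "two_point"), ...) {
  model <- match.arg(model)
  if (nrow(profiles) == 0) oed_stop("empty profile list")
  if (anyDuplicated(profiles$case_id)) {
    oed_stop(sprintf("duplicate case_id in profiles: %s",
                     paste(unique(profiles$case_id[duplicated(profiles$case_id)]),
                           collapse = ", ")))
  }
  res <- switch(model,
                six_point = six_point_score(profiles, ...),
                two_point = two_point_score(profiles))
  res <- res[order(res$case_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "stratum_counts") <- table(res$stratum)
  res
}
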