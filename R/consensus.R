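#' Majority-rule consensus feature profiles
#'
#' Calls a feature present for a case when at least `min_agree` raters
#' scored it 1. The default is a strict majority of the panel's raters
#' (2 of 3 for a three-rater panel). Missing assessments reduce the
#' number of available votes but never the threshold; a message is
#' emitted when this happens.
#'
#' @param panel A [rating_panel].
#' @param min_agree Minimum number of raters scoring 1 for a feature to
#'   be called present; default `floor(r/2) + 1` (strict majority).
#' @return A data frame of class `oed_profile` with columns `case_id`,
#'   `source` ("consensus" or "rater:<id>") and one 0/1 column per
#'   feature.
#' @examples
#' p <- panel_from_matrix(rbind(c(1, 1, 0), c(0, 0, 0), c(1, 1, 1)),
#'                        features = "verrucous_surface")
#' consensus_profile(p)$verrucous_surface  # 1 0 1
#' @export
consensus_profile <- function(panel, min_agree = NULL) {
  stopifnot(inherits(panel, "rating_panel"))
  r <- length(panel$raters)
  if (is.null(min_agree)) min_agree <- floor(r / 2) + 1L
  if (min_agree < 1 || min_agree > r) {
    oed_stop(sprintf("min_agree must be between 1 and the number of raters (%d)", r))
  }
  n_missing <- sum(is.na(panel$assessments))
  if (n_missing > 0) {
    message(sprintf(
      "consensus_profile: %d missing assessment(s); present calls use the available raters against the unchanged threshold %d",
      n_missing, min_agree))
  }
  # votes per (case, feature)
  votes <- apply(panel$assessments, c(1, 3), function(v) sum(v == 1, na.rm = TRUE))
  if (length(panel$features) == 1) votes <- matrix(votes, ncol = 1)
  calls <- (votes >= min_agree) * 1L
  out <- data.frame(case_id = panel$cases, source = "consensus",
                    stringsAsFactors = FALSE)
  for (j in seq_along(panel$features)) out[[panel$features[j]]] <- calls[, j]
  class(out) <- c("oed_profile", "data.frame")
  out
}

#' Single-rater feature profiles
#'
#' Extracts one rater's assessments in the same shape as
#' [consensus_profile()], so every downstream operation (scoring,
#' incidence, AUROC) accepts either.
#'
#' @param panel A [rating_panel].
#' @param rater_id Rater identifier present in the panel.
#' @return An `oed_profile` data frame with `source = "rater:<id>"`.
#'   Missing assessments are treated as absent (no vote).
#' @export
rater_profile <- function(panel, rater_id) {
  stopifnot(inherits(panel, "rating_panel"))
  if (!rater_id %in% panel$raters) {
    oed_stop(sprintf("unknown rater '%s' (panel has: %s)", rater_id,
                     paste(panel$raters, collapse = ", ")))
  }
  m <- panel$assessments[, match(rater_id, panel$raters), , drop = FALSE]
  calls <- (m == 1) * 1L
  calls[is.na(calls)] <- 0L
  out <- data.frame(case_id = panel$cases,
                    source = paste0("rater:", rater_id),
                    stringsAsFactors = FALSE)
  for (j in seq_along(panel$features)) out[[panel$features[j]]] <- calls[, 1, j]
  class(out) <- c("oed_profile", "data.frame")
  out
}

#' Write feature profiles to CSV
#'
#' @param profiles An `oed_profile` data frame.
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
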