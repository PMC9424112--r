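#' Canonical OED feature vocabulary
#'
#' The twelve prominent architectural and cytological features of oral
#' epithelial dysplasia used throughout the package, as snake_case
#' identifiers mapped to their display names. The vocabulary is the
#' default contract for rating CSVs; extra features can be admitted with
#' `allow_extra = TRUE` in [read_ratings()].
#'
#' @format Named character vector: names are canonical identifiers,
#'   values are display names.
#' @export
OED_FEATURES <- c(
  basal_cell_hyperplasia      = "Basal cell hyperplasia",
  bulbous_rete_pegs           = "Bulbous/drop shaped rete pegs",
  dyskeratosis                = "Dyskeratosis",
  hyperchromatism             = "Hyperchromatism",
  irregular_surface_keratin   = "Irregular surface keratin",
  loss_of_epithelial_cohesion = "Loss of epithelial cohesion",
  loss_of_stratification      = "Loss of stratification",
  suprabasal_mitoses          = "Suprabasal mitoses",
  nuclear_pleomorphism        = "Nuclear pleomorphism",
  abrupt_orthokeratosis       = "Abrupt orthokeratosis",
  lymphocytic_band            = "Lymphocytic band",
  verrucous_surface           = "Verrucous surface"
)

#' Scoring feature sets
#'
#' `SIX_POINT_FEATURES`: the six features entering the six-point
#' prognostic score (one point each). `TWO_POINT_FEATURES`: the reduced
#' two-feature set with the best inter-rater agreement among them.
#'
#' @format Character vectors of canonical feature identifiers.
#' @export
SIX_POINT_FEATURES <- c(
  "bulbous_rete_pegs", "hyperchromatism", "loss_of_epithelial_cohesion",
  "loss_of_stratification", "suprabasal_mitoses", "nuclear_pleomorphism"
)

#' @rdname SIX_POINT_FEATURES
#' @export
TWO_POINT_FEATURES <- c("loss_of_epithelial_cohesion", "bulbous_rete_pegs")

#' Canonical feature identifiers
#'
#' @return Character vector of the twelve canonical feature identifiers.
#' @export
oed_features <- function() names(OED_FEATURES)

#' Display name for a canonical feature identifier
#'
#' @param feature Canonical identifier(s).
#' @return Display name(s); the identifier itself for features outside
#'   the built-in vocabulary.
#' @export
feature_label <- function(feature) {
  out <- unname(OED_FEATURES[feature])
  out[is.na(out)] <- feature[is.na(out)]
  out
}

# snake_case normalisation used for matching, not for display
snakeify <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

# alias table: canonical id <- snakeified display name or the id itself
feature_alias_map <- function() {
  ids <- names(OED_FEATURES)
  stats::setNames(c(ids, ids), c(ids, snakeify(unname(OED_FEATURES))))
}

#' Canonicalise feature names
#'
#' Case-insensitive mapping of free-text feature names (identifiers or
#' display names) onto the canonical vocabulary. Unknown names are an
#' error unless `allow_extra = TRUE`, in which case they are kept as
#' their snake_case form.
#'
#' @param x Character vector of feature names.
#' @param allow_extra Admit names outside the built-in vocabulary?
#' @return Character vector of canonical identifiers.
#' @export
canonical_feature <- function(x, allow_extra = FALSE) {
  alias <- feature_alias_map()
  key <- snakeify(x)
  out <- unname(alias[key])
  unknown <- is.na(out)
  if (any(unknown)) {
    if (!allow_extra) {
      oed_stop(sprintf(
        "unknown feature name(s): %s (set allow_extra = TRUE to admit them)",
        paste(unique(x[unknown]), collapse = ", ")))
    }
    out[unknown] <- key[unknown]
  }
  out
}
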