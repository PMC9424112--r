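#' Multi-rater rating panel
#'
#' A `rating_panel` holds one binary assessment (present = 1, absent = 0,
#' or missing = `NA`) per (case, rater, feature) triple, stored as a
#' 3-dimensional integer array. It is the raw unit for consensus calling
#' and inter-rater agreement.
#'
#' @param data Long-format data frame with columns `case_id`, `rater_id`,
#'   `feature`, `present` (0/1, `NA` allowed for missing).
#' @param allow_extra Admit features outside the canonical vocabulary?
#' @param features Optional explicit feature ordering; defaults to
#'   canonical-vocabulary order followed by extras in order of appearance.
#' @return An object of class `rating_panel` with elements `cases`,
#'   `raters`, `features` (ordered identifier vectors) and `assessments`
#'   (case x rater x feature integer array).
#' @examples
#' df <- expand.grid(case_id = c("c1", "c2"), rater_id = c("A", "B", "C"),
#'                   feature = "verrucous_surface", stringsAsFactors = FALSE)
#' df$present <- c(1, 0, 1, 0, 1, 0)
#' p <- rating_panel(df)
#' dim(p$assessments)
#' @export
rating_panel <- function(data, allow_extra = FALSE, features = NULL) {
  required <- c("case_id", "rater_id", "feature", "present")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    oed_stop(sprintf("ratings schema error: missing column(s) %s",
                     paste(missing_cols, collapse = ", ")),
             class = "oedprog_schema_error")
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$case_id <- as.character(data$case_id)
  data$rater_id <- as.character(data$rater_id)
  data$feature <- canonical_feature(as.character(data$feature), allow_extra)

  bad <- !(data$present %in% c(0L, 1L) | is.na(data$present))
  if (any(bad)) {
    oed_stop(sprintf(
      "ratings parse error: 'present' must be 0, 1 or missing (rows %s)",
      paste(utils::head(which(bad), 5), collapse = ", ")),
      class = "oedprog_parse_error")
  }

  key <- paste(data$case_id, data$rater_id, data$feature, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    keys <- unique(paste0("(", data$case_id[dup], ", ", data$rater_id[dup],
                          ", ", data$feature[dup], ")"))
    oed_stop(sprintf("duplicate (case, rater, feature) assessment(s): %s",
                     paste(utils::head(keys, 5), collapse = "; ")))
  }

  cases <- unique(data$case_id)
  raters <- unique(data$rater_id)
  seen <- unique(data$feature)
  if (is.null(features)) {
    features <- c(intersect(oed_features(), seen),
                  setdiff(seen, oed_features()))
  } else {
    features <- canonical_feature(features, allow_extra = TRUE)
    extra <- setdiff(seen, features)
    if (length(extra) > 0) {
      oed_stop(sprintf("features present in data but not in declared order: %s",
                       paste(extra, collapse = ", ")))
    }
  }

  arr <- array(NA_integer_, dim = c(length(cases), length(raters), length(features)),
               dimnames = list(case = cases, rater = raters, feature = features))
  if (nrow(data) > 0) {
    idx <- cbind(match(data$case_id, cases),
                 match(data$rater_id, raters),
                 match(data$feature, features))
    arr[idx] <- as.integer(data$present)
  }
  new_rating_panel(cases, raters, features, arr)
}

# low-level constructor; assumes a well-formed dimnamed array
new_rating_panel <- function(cases, raters, features, assessments) {
  structure(list(cases = as.character(cases), raters = as.character(raters),
                 features = as.character(features), assessments = assessments),
            class = "rating_panel")
}

#' Build a rating panel from a case x rater 0/1 matrix for one feature,
#' or a case x rater x feature array for several.
#'
#' @param x Matrix (cases x raters) or 3-d array (cases x raters x features)
#'   of 0/1/NA assessments.
#' @param features Feature identifier(s); recycled names are invented when
#'   absent.
#' @return A `rating_panel`.
#' @export
panel_from_matrix <- function(x, features = NULL) {
  if (length(dim(x)) == 2) {
    x <- array(x, dim = c(dim(x), 1))
  }
  n <- dim(x)[1]; r <- dim(x)[2]; f <- dim(x)[3]
  if (is.null(features)) {
    features <- dimnames(x)[[3]] %||% paste0("feature_", seq_len(f))
  }
  cases <- dimnames(x)[[1]] %||% sprintf("case_%03d", seq_len(n))
  raters <- dimnames(x)[[2]] %||% paste0("rater_", LETTERS[seq_len(r)])
  arr <- array(as.integer(x), dim = c(n, r, f),
               dimnames = list(case = cases, rater = raters, feature = features))
  bad <- !(arr %in% c(0L, 1L) | is.na(arr))
  if (any(bad)) oed_stop("assessments must be 0, 1 or NA")
  new_rating_panel(cases, raters, features, arr)
}

#' @export
print.rating_panel <- function(x, ...) {
  cat(sprintf("rating_panel: %d cases x %d raters x %d features (%d missing)\n",
              length(x$cases), length(x$raters), length(x$features),
              sum(is.na(x$assessments))))
  invisible(x)
}

#' @export
as.data.frame.rating_panel <- function(x, ...) {
  g <- expand.grid(case_id = x$cases, rater_id = x$raters, feature = x$features,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$present <- as.vector(x$assessments)
  g <- g[!is.na(g$present), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Read a long-format ratings CSV
#'
#' Expects columns `case_id,rater_id,feature,present` with `present`
#' in 0/1 (empty for missing). Duplicate (case, rater, feature) rows and
#' unknown feature names (without `allow_extra`) are errors; a malformed
#' `present` value is reported with its file line number.
#'
#' @param path CSV path.
#' @inheritParams rating_panel
#' @return A [rating_panel].
#' @export
read_ratings <- function(path, allow_extra = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("case_id", "rater_id", "feature", "present")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    oed_stop(sprintf("%s: missing required column(s) %s", path,
                     paste(missing_cols, collapse = ", ")),
             class = "oedprog_schema_error")
  }
  pres <- trimws(df$present)
  pres[pres == ""] <- NA
  bad <- !(pres %in% c("0", "1")) & !is.na(pres)
  if (any(bad)) {
    # +1 for the header line
    oed_stop(sprintf("%s: malformed 'present' value at line %d (%s)",
                     path, which(bad)[1] + 1L, df$present[which(bad)[1]]),
             class = "oedprog_parse_error")
  }
  df$present <- as.integer(pres)
  rating_panel(df, allow_extra = allow_extra)
}

#' Write a rating panel to CSV (long format)
#'
#' Missing assessments are omitted; [read_ratings()] of the output
#' reproduces the panel exactly.
#'
#' @param panel A [rating_panel].
#' @param path Output CSV path.
#' @export
write_ratings <- function(panel, path) {
  stopifnot(inherits(panel, "rating_panel"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
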