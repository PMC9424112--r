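#' @name cohort
#' @title Clinical cohort table
#'
#' @description
#' A cohort is a data frame with one row per case carrying demographics,
#' histological grade, treatment, and two time-to-event outcomes
#' (malignant transformation and recurrence), all timed in months from
#' the baseline biopsy. [validate_cohort()] enforces the schema;
#' [read_cohort()]/[write_cohort()] are the CSV round-trip.
NULL

COHORT_LEVELS <- list(
  gender = c("female", "male"),
  site = c("tongue", "floor of mouth", "buccal mucosa", "gingivae",
           "hard palate", "lower lip", "soft palate"),
  who_grade = c("mild", "moderate", "severe"),
  binary_grade = c("low", "high"),
  treatment = c("monitored", "excised", "laser")
)

COHORT_COLUMNS <- c("case_id", "age", "gender", "site", "who_grade",
                    "binary_grade", "treatment",
                    "transformation_event", "transformation_time",
                    "recurrence_event", "recurrence_time", "followup_time")

# months defining "minimum five-year follow-up" for censored cases
MIN_FOLLOWUP <- 60

#' Validate a cohort data frame
#'
#' Checks the column schema, categorical levels, positivity of age and
#' times, binary event indicators, `event time <= followup_time`, and —
#' in strict mode — that cases with neither event have at least 60
#' months (five years) of follow-up, mirroring the minimum-follow-up
#' inclusion rule of the study design.
#'
#' @param cohort Data frame to validate.
#' @param strict Enforce the 60-month minimum follow-up rule for
#'   event-free cases (default `TRUE`).
#' @return The validated data frame, invisibly coerced to canonical
#'   column types.
#' @export
validate_cohort <- function(cohort, strict = TRUE) {
  cohort <- as.data.frame(cohort, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols) > 0) {
    oed_stop(sprintf("cohort schema error: missing column(s) %s",
                     paste(missing_cols, collapse = ", ")),
             class = "oedprog_schema_error")
  }
  cohort$case_id <- as.character(cohort$case_id)
  if (anyDuplicated(cohort$case_id)) {
    oed_stop(sprintf("duplicate case_id: %s",
                     paste(unique(cohort$case_id[duplicated(cohort$case_id)]),
                           collapse = ", ")))
  }
  for (col in names(COHORT_LEVELS)) {
    val <- tolower(trimws(as.character(cohort[[col]])))
    bad <- !(val %in% COHORT_LEVELS[[col]])
    if (any(bad)) {
      oed_stop(sprintf("unknown %s level(s): %s (case %s)", col,
                       paste(unique(val[bad]), collapse = ", "),
                       paste(utils::head(cohort$case_id[bad], 3), collapse = ", ")))
    }
    cohort[[col]] <- val
  }
  num_cols <- c("age", "transformation_time", "recurrence_time", "followup_time")
  for (col in num_cols) cohort[[col]] <- as.numeric(cohort[[col]])
  for (col in c("transformation_event", "recurrence_event")) {
    v <- as.numeric(cohort[[col]])
    if (!all(v %in% c(0, 1))) {
      oed_stop(sprintf("%s must be 0/1", col))
    }
    cohort[[col]] <- as.integer(v)
  }
  if (any(is.na(cohort$age)) || any(cohort$age <= 0)) {
    oed_stop("age must be a positive number for every case")
  }
  for (ev in c("transformation", "recurrence")) {
    evc <- cohort[[paste0(ev, "_event")]]
    tmc <- cohort[[paste0(ev, "_time")]]
    if (any(evc == 1 & is.na(tmc))) {
      oed_stop(sprintf("%s_event = 1 with missing %s_time (case %s)", ev, ev,
                       paste(cohort$case_id[evc == 1 & is.na(tmc)], collapse = ", ")))
    }
    if (any(!is.na(tmc) & tmc <= 0)) {
      oed_stop(sprintf("%s_time must be > 0", ev))
    }
    over <- !is.na(tmc) & tmc > cohort$followup_time + 1e-9
    if (any(over)) {
      oed_stop(sprintf("%s_time exceeds followup_time for case %s", ev,
                       paste(utils::head(cohort$case_id[over], 5), collapse = ", ")))
    }
  }
  if (any(is.na(cohort$followup_time)) || any(cohort$followup_time <= 0)) {
    oed_stop("followup_time must be a positive number for every case")
  }
  if (strict) {
    censored <- cohort$transformation_event == 0 & cohort$recurrence_event == 0
    short <- censored & cohort$followup_time < MIN_FOLLOWUP
    if (any(short)) {
      oed_stop(sprintf(
        "case(s) %s are event-free with < %d months follow-up; excluded under the minimum five-year follow-up rule (set strict = FALSE to keep them)",
        paste(utils::head(cohort$case_id[short], 5), collapse = ", "),
        MIN_FOLLOWUP))
    }
  }
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' @param path CSV path with the columns listed under [validate_cohort()].
#' @param strict Enforce the minimum follow-up rule (default `TRUE`).
#' @return Validated cohort data frame.
#' @export
read_cohort <- function(path, strict = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df, strict = strict)
}

#' Write a cohort CSV
#'
#' @param cohort Validated cohort data frame.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort[, COHORT_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
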