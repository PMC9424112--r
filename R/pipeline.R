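#' Run the full analysis pipeline
#'
#' Orchestrates one end-to-end study analysis: obtain data (from input
#' CSVs or the synthetic generator), call consensus profiles, compute
#' the agreement table, the feature incidence table, univariate Cox
#' hazard ratios, Kaplan-Meier risks at 2 and 5 years per score
#' stratum, and the AUROC evaluation (score-only, grade-only,
#' covariate-augmented, model-vs-grade comparisons, per-rater table).
#' Every default applied is logged via `message()`.
#'
#' @param config A list, or path to a YAML file, with keys:
#'   * `inputs`: list with `ratings` and `cohort` CSV paths, **or**
#'   * `simulate`: list of [generator_config()] overrides;
#'   * `seed`: integer seed (required with `simulate`);
#'   * `min_agree`: consensus threshold (default strict majority);
#'   * `models`: subset of `c("six_point", "two_point")` (default both);
#'   * `covariate_sets`: list of covariate subsets for augmented models
#'     (default age+gender, who_grade, binary_grade).
#'   Unknown keys are rejected.
#' @param out_dir Optional directory; when given, [write_report()] is
#'   called on the bundle.
#' @return A report bundle (list) with elements `agreement`,
#'   `incidence`, `cox`, `km_risks`, `auroc`, `meta`. All elements are
#'   plain data frames/lists, JSON-serialisable; the bundle is the
#'   single source of truth for [write_report()].
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("inputs", "simulate", "seed", "min_agree", "models",
             "covariate_sets")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    oed_stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  models <- config$models %||% c("six_point", "two_point")
  covariate_sets <- config$covariate_sets %||%
    list(c("age", "gender"), "who_grade", "binary_grade")

  truth <- NULL
  if (!is.null(config$inputs)) {
    message("pipeline: reading ratings from ", config$inputs$ratings)
    panel <- read_ratings(config$inputs$ratings)
    cohort <- read_cohort(config$inputs$cohort)
    seed <- config$seed %||% NA_integer_
  } else {
    sim_args <- config$simulate %||% list()
    if (!is.null(config$seed)) sim_args$seed <- config$seed
    gcfg <- do.call(generator_config, sim_args)
    message("pipeline: simulating study (n = ", gcfg$n_cases,
            ", seed = ", gcfg$seed, ")")
    sim <- generate(gcfg)
    panel <- sim$panel; cohort <- sim$cohort; truth <- sim$truth
    seed <- gcfg$seed
  }

  min_agree <- config$min_agree %||% (floor(length(panel$raters) / 2) + 1L)
  message("pipeline: consensus threshold min_agree = ", min_agree)
  profiles <- consensus_profile(panel, min_agree = min_agree)

  agreement <- agreement_table(panel)
  incidence <- incidence_table(cohort, profiles)
  cox_tab <- univariate_feature_cox(cohort, profiles)

  km_risks <- list()
  scores <- list()
  for (model in models) {
    sc <- score_cohort(profiles, model = model)
    scores[[model]] <- sc
    strat <- stats::setNames(as.character(sc$stratum), sc$case_id)
    for (ev in c("transformation", "recurrence")) {
      km <- suppressWarnings(km_fit(cohort, ev, strata = strat))
      rk <- km_risk(km, times = c(24, 60))
      rk$model <- model
      rk$event <- ev
      km_risks[[paste(model, ev, sep = ".")]] <- rk
    }
  }
  km_risks <- do.call(rbind, km_risks)
  rownames(km_risks) <- NULL

  # AUROC: scores, grades, covariate-augmented models, comparisons
  auroc_rows <- list()
  comparison_rows <- list()
  for (ev in c("transformation", "recurrence")) {
    y <- cohort[[paste0(ev, "_event")]]
    grade_scores <- list(
      who_grade = encode_covariates(cohort, "who_grade")$who_grade,
      binary_grade = encode_covariates(cohort, "binary_grade")$binary_grade)
    rocs <- list()
    for (model in models) {
      sc <- scores[[model]]
      s <- sc$score[match(cohort$case_id, sc$case_id)]
      rocs[[model]] <- auroc(s, y, label = model, case_id = cohort$case_id)
      for (cs in covariate_sets) {
        aug <- augmented_model_auroc(cohort, s, cs, ev,
                                     label = paste(c(model, cs), collapse = " + "))
        auroc_rows[[length(auroc_rows) + 1]] <- data.frame(
          event = ev, predictor = aug$label, auc = aug$auc,
          stringsAsFactors = FALSE)
      }
    }
    for (g in names(grade_scores)) {
      rocs[[g]] <- auroc(grade_scores[[g]], y, label = g,
                         case_id = cohort$case_id)
    }
    for (nm in names(rocs)) {
      auroc_rows[[length(auroc_rows) + 1]] <- data.frame(
        event = ev, predictor = nm, auc = rocs[[nm]]$auc,
        stringsAsFactors = FALSE)
    }
    for (model in intersect(models, names(rocs))) {
      for (g in names(grade_scores)) {
        cmp <- compare_auroc(rocs[[model]], rocs[[g]])
        comparison_rows[[length(comparison_rows) + 1]] <- data.frame(
          event = ev, model = model, reference = g,
          auc_model = cmp$auc_a, auc_reference = cmp$auc_b,
          diff = cmp$diff, p = cmp$p, stringsAsFactors = FALSE)
      }
    }
  }
  auroc_tab <- do.call(rbind, auroc_rows)
  comparisons <- do.call(rbind, comparison_rows)
  per_rater <- per_rater_evaluation(panel, cohort, models = models,
                                    min_agree = min_agree)

  bundle <- list(
    agreement = agreement,
    incidence = incidence,
    cox = cox_tab,
    km_risks = km_risks,
    auroc = list(table = auroc_tab, comparisons = comparisons,
                 per_rater = per_rater),
    meta = list(n_cases = nrow(cohort), n_raters = length(panel$raters),
                min_agree = min_agree, models = models, seed = seed,
                simulated = is.null(config$inputs))
  )
  if (!is.null(out_dir)) write_report(bundle, out_dir)
  bundle
}

#' Write a report bundle to disk
#'
#' Serialises the bundle to `bundle.json` plus one CSV per table
#' (`agreement.csv`, `incidence.csv`, `cox.csv`, `km_risks.csv`,
#' `auroc.csv`, `auroc_comparisons.csv`, `per_rater.csv`). The CSVs are
#' derived from the bundle alone, so regenerating from `bundle.json`
#' reproduces them exactly.
#'
#' @param bundle A [run_pipeline()] bundle (or one re-read from
#'   `bundle.json` with `jsonlite::read_json(..., simplifyVector = TRUE)`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(bundle, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  tabs <- list(agreement = bundle$agreement, incidence = bundle$incidence,
               cox = bundle$cox, km_risks = bundle$km_risks,
               auroc = bundle$auroc$table,
               auroc_comparisons = bundle$auroc$comparisons,
               per_rater = bundle$auroc$per_rater)
  for (nm in names(tabs)) {
    utils::write.csv(as.data.frame(tabs[[nm]]), file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
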