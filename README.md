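# oedprog

Feature-count prognostic models for oral epithelial dysplasia (OED).

OED is a precursor state of oral squamous cell carcinoma. Its histological
grading (WHO three-tier, or binary low/high) is subjective and a weak
predictor of which lesions will transform or recur. An alternative is to
score individual architectural and cytological features — each called
present/absent by several pathologists — and count them. `oedprog`
implements that analysis end to end for researchers working with
multi-rater feature panels and time-to-event follow-up:

* **Consensus calling** — a feature is present when a majority of raters
  (2 of 3 by default) scored it prominent; single-rater profiles share the
  same interface so per-rater analyses are first-class.
* **Inter-rater agreement** — per feature: pooled prevalence π, observed
  pairwise agreement `Pa`, complete agreement, and two chance-corrected
  coefficients with chance terms built from the pooled marginals:

  - Fleiss-type kappa: `Pe = π² + (1−π)²`, `κ = (Pa − Pe)/(1 − Pe)`
  - Gwet's AC1: `Pe = 2π(1−π)`, `AC1 = (Pa − Pe)/(1 − Pe)`

  For three binary raters the pair (positive assessments, unanimous cases)
  determines every statistic in closed form, so published agreement tables
  can be reproduced exactly from their printed marginals
  (`panel_from_marginals()`).
* **Prognostic scores** — the six-point model (one point each for bulbous
  rete pegs, hyperchromatism, loss of epithelial cohesion, loss of
  stratification, suprabasal mitoses, nuclear pleomorphism; strata 0–1 /
  2–3 / 4–6) and the reduced two-point model (loss of epithelial cohesion,
  bulbous rete pegs; strata by presence pattern).
* **Survival analysis** — Kaplan–Meier risk per stratum (Greenwood
  variance, log(−log) 95% intervals, 2- and 5-year risks) and Cox
  proportional-hazards regression with Efron's correction for tied times,
  via the `survival` package.
* **Discrimination** — AUROC by the midrank Mann–Whitney statistic for the
  binary "event at any time" outcome, DeLong tests for correlated AUCs,
  logistic covariate-augmented models (age, gender, grade), and per-rater
  performance tables.
* **Synthetic cohorts** — a generator of full studies (latent feature
  vectors, noisy raters, covariates, two exponential time-to-event
  outcomes with feature-multiplicative hazards) calibrated by default to
  the 109-case cohort scale: ~18% transformation and ~25% recurrence by 5
  years, Table-level feature prevalences and hazard-ratio magnitudes.

## Worked example

Simulate a 109-case, 3-rater study at the default calibration and run the
analysis:

```r
library(oedprog)
sim    <- generate(generator_config(seed = 2024))
prof   <- consensus_profile(sim$panel)         # 2-of-3 majority rule
tab    <- agreement_table(sim$panel)
format_agreement_table(tab)[c(2, 6, 12), ]
#>                          feature prevalence complete_agreement kappa  ac1
#> 2  Bulbous/drop shaped rete pegs  168 (51%)           75 (69%)  0.58 0.58
#> 6    Loss of epithelial cohesion  114 (35%)           77 (71%)  0.57 0.64
#> 12             Verrucous surface  108 (33%)           72 (66%)  0.49 0.59
```

Prevalence is positive assessments out of 327 (109 cases × 3 raters);
complete agreement is the number of cases where all three raters concur;
kappa/AC1 are the chance-corrected coefficients above. Score the cohort
and estimate stratum risks:

```r
sc <- score_cohort(prof, "six_point")
attr(sc, "stratum_counts")
#> 0-1 2-3 4-6
#>  25  67  17
km <- km_fit(sim$cohort, "transformation",
             strata = setNames(as.character(sc$stratum), sc$case_id))
km_risk(km, times = c(24, 60))
#>   stratum time      risk      lower     upper
#> 5     4-6   24 0.1764706 0.06059466 0.4528682
#> 6     4-6   60 0.7058824 0.48851513 0.8928800   # (0-1 / 2-3 rows omitted)
```

`risk` is 1 − S(t) at 2 and 5 years with its 95% interval: in this draw,
high-scoring (4–6) lesions carry a 71% five-year transformation risk. A
univariate Cox fit and model comparison:

```r
cox_fit(sim$cohort, "transformation", prof[, c("case_id", "bulbous_rete_pegs")])
#> Cox PH (Efron ties), event = transformation, n = 109, events = 29
#>               term                  hr            p
#>  bulbous_rete_pegs 15.19 (3.61, 63.96) 0.0002077776

s  <- sc$score[match(sim$cohort$case_id, sc$case_id)]
r6 <- auroc(s, sim$cohort$transformation_event, label = "six_point")
who <- match(sim$cohort$who_grade, c("mild", "moderate", "severe"))
cmp <- compare_auroc(r6, auroc(who, sim$cohort$transformation_event))
#> six-point AUC 0.841 vs WHO-grade AUC 0.646, DeLong p = 0.0012
```

The feature-count score discriminates transformation markedly better than
the WHO grade in this strong-signal draw, and the DeLong test shows the
paired difference is unlikely under equal AUCs. `run_pipeline()` wraps all
of the above (agreement, incidence, Cox, KM risks, AUROC tables, per-rater
performance) into one reproducible report bundle written as CSV + JSON.

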