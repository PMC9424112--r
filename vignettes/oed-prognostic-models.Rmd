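---
title: "Feature-count prognostic models for oral epithelial dysplasia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-count prognostic models for oral epithelial dysplasia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oedprog)
```

# The problem

Oral epithelial dysplasia (OED) is graded histologically to estimate the
risk that a lesion transforms to squamous cell carcinoma or recurs after
treatment. Grading aggregates many ill-defined features into one ordinal
label, which makes it both poorly reproducible between pathologists and a
weak prognostic predictor. The alternative implemented here decomposes the
problem: several raters score individual architectural and cytological
features as present/absent, a consensus call per feature is derived, and
simple feature-count scores are evaluated against time-to-event outcomes.

`oedprog` covers that workflow end to end: data contracts and validation,
consensus calling, inter-rater agreement, the two feature-count scores,
Kaplan–Meier and Cox survival analysis, AUROC-based model comparison, and
a synthetic-cohort generator that closes the loop by letting every
estimator be checked against known truth.

# Data model

A **rating panel** is one ternary value (present = 1 / absent = 0 /
missing) per (case, rater, feature). The twelve-feature vocabulary
(`OED_FEATURES`) is built in; CSVs may use display names or snake_case
identifiers, matched case-insensitively, and extra features can be
admitted explicitly. A **cohort** row carries age, gender, intraoral
site, WHO and binary grade, treatment, and two outcomes — transformation
and recurrence — each as an event indicator and a time in months from the
baseline biopsy, plus the total follow-up time.

Two validation rules deserve note:

* *Time origin.* Months from baseline biopsy for both outcomes. The
  choice of biopsy date (rather than treatment date) as origin is a
  convention of this package; it matches how minimum-follow-up inclusion
  rules are stated for diagnostic cohorts and is applied uniformly.
* *Minimum follow-up.* In strict mode (the default), an event-free case
  must have at least 60 months of follow-up, mirroring the
  five-year-minimum inclusion rule of retrospective OED cohorts. Cases
  with an event are never excluded by this rule.

Missing assessments are allowed by the type (real-world panels have
them), handled by pairwise deletion in agreement statistics and by
reduced vote counts in consensus calling; complete panels are unaffected.

# Consensus calling

A feature is present when at least `min_agree` raters scored it 1. The
default is a strict majority, `floor(r/2) + 1` — 2 of 3 for the canonical
three-rater panel. With an even number of raters a tie is therefore a
*negative* call; we prefer this over `ceil(r/2)` because presence should
require more raters in favour than against, and it reduces to the same
threshold for odd panels. Missing assessments reduce the available votes
but never the threshold (a case with one of three raters missing still
needs 2 positive votes), and a message records when this path is taken.

# Agreement statistics

For case $i$ let $m_i$ be its non-missing assessments and $k_i$ its
positive ones. Observed pairwise agreement pools agreeing rater pairs
over available pairs:

$$P_a = \frac{\sum_i \binom{k_i}{2} + \binom{m_i-k_i}{2}}
             {\sum_i \binom{m_i}{2}},$$

which for complete three-rater binary data reduces to
$(U + (n-U)/3)/n$ with $U$ unanimous cases — every non-unanimous case is
a 2–1 split contributing exactly 1/3. With pooled prevalence
$\pi = \sum k_i / \sum m_i$, chance agreement is
$\pi^2 + (1-\pi)^2$ (Fleiss-type kappa) or $2\pi(1-\pi)$ (Gwet's AC1),
and each coefficient is $(P_a - P_e)/(1 - P_e)$.

Design choices:

* A "multi-rater Cohen's kappa" is ambiguous; we implement the
  Fleiss-type pooled-marginal form as the default because it is the
  standard multi-rater generalisation and reproduces published
  agreement tables from their marginals. Mean pairwise Cohen's kappa
  (rater-specific marginals) is available as
  `multirater_kappa(..., method = "pairwise_cohen")` for comparison.
* AC1's chance term is capped at 1/2 for binary data, so AC1 is always
  defined; kappa degenerates when $\pi \in \{0, 1\}$ and is returned as
  `NaN` with a warning rather than a fabricated value.
* Report rounding is 2 decimal places, half away from zero
  (`round_half_up()`), matching how such tables are printed.

Because (positives, unanimous) determine everything for three raters,
`panel_from_marginals()` reconstructs a concrete panel from printed
marginals; the package's tests use it to reproduce published
coefficients exactly. No variances or confidence intervals are attached
to kappa/AC1 (none are needed for the reproduction), and weighted or
ordinal agreement is out of scope.

# The prognostic scores

The **six-point score** counts the presence of bulbous/drop-shaped rete
pegs, hyperchromatism, loss of epithelial cohesion, loss of
stratification, suprabasal mitoses and nuclear pleomorphism — the six
features whose univariate hazard ratios are large and similar enough
that equal weights are defensible; its canonical strata are 0–1, 2–3 and
4–6 points. The cut-points are arguments (threshold exploration belongs
in the evaluation layer), but the defaults are the model's definition.
The **two-point score** keeps the two features with the best inter-rater
agreement among the six (loss of epithelial cohesion, bulbous rete
pegs); its strata are the four presence patterns, because the two
single-feature groups behave differently and collapsing them to "score
1" would hide that. No regression-derived weights are fitted anywhere —
the models are deliberately point-count models.

# Survival analysis

Kaplan–Meier curves per stratum come from `survival::survfit` with
Greenwood variance and 95% intervals on the $\log(-\log S)$ scale. The
log(−log) transform is chosen because it keeps intervals inside [0, 1]
and yields the asymmetric intervals typical of published five-year risk
estimates. `km_risk()` reads off $1 - S(t)$ at 24 and 60 months. A
stratum with zero events is returned flagged, not dropped.

Cox regression uses `survival::coxph` with `ties = "efron"`. Efron's
correction matters here because follow-up is recorded in whole months,
so tied event times are common; with no ties it coincides with the exact
partial likelihood, which the test suite verifies against an independent
hand-written maximiser. Reported intervals are Wald,
$\exp(\hat\beta \pm 1.96\,\mathrm{se})$, and p-values are two-sided Wald
tests — consistent with presenting HR + CI. Only univariate per-feature
fits are exposed as a table (`univariate_feature_cox()`); a joint model
over all features is used internally only for generator calibration
checks (see below). Constant covariates are reported as
non-identifiable rather than crashing the table; warnings suggestive of
monotone likelihood are captured and attached as flags.

# Discrimination analysis

Prognostic performance is assessed on the binary outcome "event at any
time during follow-up" — not a time-dependent ROC — because few events
occur after five years in cohorts with this design, and the simpler
outcome matches how the scores would be used. AUROC is the midrank
Mann–Whitney statistic (ties count 1/2); the six-point score enters as
its raw 0–6 count, the two-point as 0–2, WHO grade as ordinal 1–3 and
binary grade as 0/1. Correlated AUCs on the same cases are compared with
the DeLong placement-value test, implemented in the package (an
identical predictor gives difference 0 and p = 1 exactly) and
cross-checked in the tests against an independent implementation.
Covariate-augmented models are in-sample logistic fits
(score + age/gender/grade) whose fitted probabilities are scored by
AUROC; there is no held-out split or optimism correction, so augmented
AUROCs are apparent performance. Under separation the fit falls back to
a lightly ridge-penalised logistic model and the result is flagged.
Whether published augmented AUROCs used logistic combination is not
stated anywhere we could rely on; logistic is this package's documented
assumption.

# The synthetic-cohort generator

The generator exists to validate the pipeline: it draws studies whose
true parameters are known, at the scale of the 109-case cohort the
models come from. Per case: a latent feature vector (independent
Bernoulli at the pooled Table-level prevalences by default); per rater:
a noisy assessment (sensitivity 0.85, specificity 0.90 by default,
chosen to land mean kappa/AC1 in the 0.5–0.6 band typical of observer
agreement on these features); covariates from the cohort's published
marginals (61% male, site and treatment frequencies, age ~ N(67, 14.8²)
truncated to [18, 95], reproducing a median of 67 with IQR ≈ 57–77);
WHO grade drawn conditionally on the latent six-point count with mixing
rows set once so the marginal lands at ≈31/44/25 mild/moderate/severe
(binary grade: severe → high, moderate → high with probability 0.2,
giving ≈33% high).

Event times are exponential with rate
$h_0 \prod_f \mathrm{HR}_f^{x_f}$ — proportional hazards by
construction, with the six prognostic features carrying their published
univariate point estimates as defaults and all other features null. Two
calibration choices matter:

* *Baseline hazard.* By default $h_0$ is solved numerically (exact
  enumeration over the $2^k$ combinations of non-null features) so that
  the marginal event probability by 60 months equals 18%
  (transformation) and 25% (recurrence) — the study-scale rates. Any
  fixed rate can be supplied instead; $h_0 = 0$ is allowed and yields a
  zero-event study that `calibration_report()` flags as degenerate.
* *Hazard-ratio semantics.* The configured HRs are conditional
  (multiplicative per feature). Univariate refits of a multi-feature
  study are therefore attenuated by marginalisation (Cox
  non-collapsibility), which is expected behaviour, not an error;
  `calibration_report()` checks recovery with one joint fit on the
  latent features. Single-feature generator configurations, as used for
  hazard-ratio recovery checks, have no such gap.

Censoring is administrative at 120 months, with a configurable fraction
(default 0.15) censored uniformly between 60 and 120 months; censored
cases therefore always satisfy the five-year minimum follow-up rule.
Times are recorded in whole months (ceiling) by default so tied event
times occur and the Efron machinery is actually exercised;
`round_times = FALSE` gives continuous times. Transformation and
recurrence are independent given the features, and features are
independent by default — a shared latent severity factor
(`severity_sd > 0`) can induce the positive co-occurrence of atypia
seen in real lesions, but no published covariance exists to calibrate
it, so it is off by default. The generator does not model
treatment-dependent hazards, so it cannot reproduce the observed
anomaly of moderate-grade lesions transforming more often than severe
ones, which has been attributed to treatment differences; nor does it
model per-site effects.

What passing tests on generated data do and do not show: they verify
the estimators (agreement closed forms, product-limit arithmetic,
partial-likelihood maximisation, AUROC and its comparison test) and the
pipeline's plumbing under a correctly specified model. They do not show
that real OED panels satisfy proportional hazards, feature
independence, or homogeneous rater error — conclusions about real
cohorts still require real validation data.

# Numerical choices and degenerate inputs

* Agreement: cases with fewer than two non-missing assessments are
  excluded from a feature's statistics; prevalence uses the included
  cases' assessments.
* Cox: `survival::coxph` defaults (Newton–Raphson, convergence 1e-9);
  Wald inference with the fixed 1.96 quantile.
* KM: risk at t reads the step function at the last event time ≤ t;
  before the first event the risk is 0 with undefined interval.
* AUROC: degenerate outcomes (no events, or no non-events) are errors;
  a constant predictor gives exactly 0.5. The DeLong variance can be
  zero only when placements are constant; with zero difference that is
  reported as p = 1, otherwise flagged.
* Baseline-hazard calibration supports up to 12 non-null features
  (4096-term enumeration); beyond that, supply `baseline_hazard`
  directly.
* Ridge fallback for separated logistic fits uses `glmnet` at a fixed
  small penalty (λ = 0.01) — enough to stabilise the linear predictor's
  ordering without materially shrinking AUROC.

# Problem sizes used by the test suite

The suite runs at sizes chosen to keep Monte-Carlo error well inside the
asserted tolerances: 500 random panels for agreement-oracle equivalence,
500 random instances for AUROC-oracle equivalence, 1000 null pairs for
the DeLong size check, single n = 5000 cohorts plus 100 replicates at
n = 1000 for hazard-ratio recovery (median within 10%, interval coverage
within [0.90, 0.99]), and n ≈ 2000–5000 for law-of-large-numbers
calibration checks. All stochastic tests fix their seeds.

# Known limitations

* Agreement variances/CIs, weighted agreement and AC2 are not provided.
* No multivariable prognostic Cox model over all features is exposed;
  the models under evaluation are the point-count scores.
* Augmented AUROCs are in-sample; no cross-validation or optimism
  correction.
* The generator's exponential baseline and independence assumptions are
  conveniences for validation, not claims about OED biology.
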