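---
title: "Estimating population ADNC prevalence from plasma pTau217 under selective observation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating population ADNC prevalence from plasma pTau217 under selective observation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adncprev)
```

## The estimation problem

Plasma pTau217 is a blood biomarker of Alzheimer's disease
neuropathological change (ADNC): concentrations rise with amyloid plaque
and tau tangle burden, and agreement with post-mortem pathology is high
enough that elevated pTau217 is used as a surrogate for ADNC itself.
Estimating how common ADNC is in the general older population from a
survey cohort faces two obstacles:

1. **The biomarker is not a binary test.** A single threshold wastes the
   information in the continuous concentration and forces an unfavorable
   sensitivity/specificity trade-off.
2. **Who ends up with a measured blood sample is not random.** Older
   people, people with dementia and people with less education
   participate less and donate blood less; a sub-study may deliberately
   oversample the cognitively impaired. Raw proportions computed on the
   measured subset estimate the wrong population.

This package implements the full estimation pipeline addressing both,
plus the downstream analyses that depend on it: predictive values of the
biomarker at the estimated prevalence, the relationship of pTau217 with
kidney function, and the fraction of the population eligible for
anti-amyloid disease-modifying therapy.

## Two-cutoff classification

`classify_adnc()` classifies a concentration with a *rule-out* lower
cutoff (default 0.40 pg/ml, chosen for high sensitivity) and a *rule-in*
upper cutoff (default 0.63 pg/ml, chosen for high specificity):

* below 0.40 pg/ml: ADNC **negative** (strictly below — the boundary
  itself is not "ruled out");
* at or above 0.63 pg/ml: ADNC **positive**;
* in between: **intermediate** — an expected, intrinsic feature of a
  continuous biomarker, not a failure mode. These individuals would need
  follow-up (CSF, PET, or repeat plasma testing) in practice.

The boundary conventions (0.40 itself intermediate, 0.63 itself
positive) are configurable via `cutoff_scheme()` because the third
decimal of the boundary behavior is a convention, not biology.
Concentrations above the usual plotting range (3 pg/ml) are classified
normally. `stage_continuum()` crosses the category with the clinical
diagnosis: positive plus cognitively unimpaired = preclinical AD,
positive plus MCI = prodromal AD, positive plus dementia = AD dementia;
a negative biomarker rules the continuum out regardless of cognition,
and an intermediate biomarker or missing assessment is indeterminate.

## Multi-stage inverse-probability weighting

Selection into the measured subset happens in stages: participation in
the survey, donation of a blood sample given participation, and (for the
younger nested wave) selection into the sub-study. Each stage gets its
own logistic model on the covariates that plausibly drive it
(`default_stage_specs()`: age, sex, education for participation; plus
APOE e4 count, cognitive diagnosis and the self-reported comorbidity
flags for the later stages). Missing education or APOE values are kept
as their own category level rather than dropped — missingness itself
predicts participation.

The weight of an observed record is the inverse of the product of its
stage probabilities: two factors for the 70+ wave, three for the younger
wave (`compose_weights()`). Raw weights are then **winsorized** to
median ± 3 × IQR (`trim_weights()`, quartiles by linear interpolation
between order statistics). Trimming is clipping, not exclusion:
excluding extreme-weight records would change the estimand, while
clipping only trades a little bias for variance. A negative lower bound
is floored at the smallest positive double since weights must stay
positive. If a stage's ML fit separates (possible in small or sparse
cohorts), it is refitted with a small ridge penalty
(glmnet, alpha = 0, lambda = 1e-4) and flagged — never silently.

## Weighted prevalence and its uncertainty

`weighted_proportion()` is the Hajek estimator
$\hat p = \sum w_i x_i / \sum w_i$. The default interval is a **Wilson
interval computed on the Kish effective sample size**
$n_\mathrm{eff} = (\sum w)^2/\sum w^2$: it respects $[0,1]$, is cheap,
and penalizes weight variability. A percentile bootstrap over records is
available behind `ci_method = "bootstrap"` for users who prefer a
resampling interval; both are interpretations, since a weighted-CI
method is a genuine methodological choice. The same effective-sample
scaling is applied before Pearson's chi-squared formula in
`proportion_test()`, because naively summed weighted counts inflate the
statistic. Coverage of the Wilson/$n_\mathrm{eff}$ interval under
estimated weights is verified by simulation in the test suite (200
replicates; at least 93% required). `prevalence_table()` assembles the
stratified tables (age group, sex, education, diagnosis, with marginal
rows); empty strata are emitted with zero counts rather than dropped.

`comorbidity_association()` fits a weighted logistic regression of
biomarker positivity (positive vs negative-or-intermediate — the
dichotomy that matches "concentration above the upper cutoff") on one
comorbidity flag adjusted for age, sex, APOE e4 count, cognition, serum
creatinine and education, with weights rescaled to sum to
$n_\mathrm{eff}$ so Wald intervals are not spuriously narrow.

## Predictive values on a sensitivity/specificity grid

PPV and NPV depend on prevalence through Bayes' formulas

$$\mathrm{PPV} = \frac{Se \cdot p}{Se \cdot p + (1-Sp)(1-p)}, \qquad
  \mathrm{NPV} = \frac{Sp(1-p)}{(1-Se)p + Sp(1-p)}.$$

Because externally reported operating characteristics come as ranges,
`grid_summary()` enumerates every (Se, Sp) pair on a closed grid
(defaults Se 0.850–0.982, Sp 0.745–0.986, step 0.001 — 133 × 242 =
32,186 points, built by integer index so no floating-point drift
accumulates), evaluates both formulas at the stratum prevalence, and
summarizes the two distributions by the median and the 2.5th/97.5th
percentiles (linear-interpolation percentiles, type 7).

**Optimism shrinkage.** External validation usually degrades reported
operating characteristics, so the analysis can be repeated with Se and
Sp contracted toward chance before the Bayes computation:
$x' = 0.5 + \lambda(x - 0.5)$ with shrinkage level $\lambda = 0.9$ by
default (`shrink_toward_chance()`). Contraction toward 0.5 — rather
than plain multiplication $x' = \lambda x$ — is the mapping under which
a test with $Se + Sp = 1$ (an uninformative test) stays uninformative;
multiplication would push an uninformative test below chance. The
mapping is a named exported function so alternatives can be swapped in.
`stratum_sweep()` repeats the summary at each age stratum's weighted
prevalence; PPV medians rise and NPV medians fall with prevalence, as
Bayes' theorem requires.

## Kidney function

Reduced glomerular filtration concentrates plasma biomarkers, so the
pipeline models log pTau217 against eGFR. `egfr_ckd_epi_2021()`
evaluates the race-free CKD-EPI 2021 creatinine equation (constants
hardcoded from the 2021 publication; mg/dl only — divide µmol/l by
88.42). `fit_segmented()` fits a continuous two-segment weighted
least-squares model with the breakpoint chosen by profile grid search
over the 5th–95th percentile interior of the observed eGFR range
(default resolution 0.1 units). Grid profiling was chosen over
Muggeo-style iterative updating because it is deterministic,
oracle-checkable and adequate at these problem sizes; SSE ties resolve
to the smallest breakpoint and set a flag. The hinge parameterization
nests the straight line, so the segmented SSE can never exceed the
single-line SSE beyond grid resolution. Natural logarithms are used
throughout; `predict_segmented()` returns fitted values back on the
pg/ml scale.

## Treatment eligibility with multiple imputation

`eligibility_criteria()` encodes the default rule: MCI or mild dementia,
biomarker positive, no history of stroke or brain haemorrhage, optional
BMI bounds. The full appropriate-use criteria for anti-amyloid therapy
are more detailed; the object is deliberately a config knob and the
default makes no claim to reproduce any specific trial's rule set.

Missing eligibility covariates (BMI, APOE e4 count, stroke history) are
completed by chained-equation multiple imputation
(`impute_missing()`, default m = 5 datasets, 5 sweeps): binary
variables by logistic draws, the three-level APOE count by multinomial
logistic draws, and continuous BMI by predictive mean matching (a draw
among the five nearest observed donors by predicted mean). Predictive
mean matching was chosen for the continuous variable as a
distribution-preserving donor draw — it cannot produce impossible BMI
values and its recovery under MCAR deletion is verified directly in the
test suite. Observed cells are never altered; each completed dataset
runs on its own seeded substream. `eligible_proportion()` divides the
weighted sum of eligible records by the weighted sum of the study
population in each completed dataset and pools by the simple average
(Rubin's point rule), reporting the between-imputation spread alongside.

## The synthetic cohort generator

Real population cohorts with clinical adjudication and biobanked plasma
are access-restricted, so the package ships `generate_cohort()`, a
generator that reproduces the *statistical structure* the estimators
must handle — not the demography of any particular study:

* ADNC prevalence follows a logistic model in age and APOE e4 count
  (defaults: intercept −1.45 at age 70, +0.085 per year, +0.9 per e4
  allele), giving roughly one-third biomarker positivity in the 70+
  population and a steep age gradient — the regime in which the
  selection-bias correction matters.
* pTau217 is a two-component log-normal mixture conditional on latent
  ADNC (defaults: meanlog log 0.25, sdlog 0.35 for negatives; meanlog
  log 0.9, sdlog 0.5 for positives), so concentrations are positive,
  right-skewed, and produce a realistic intermediate zone (roughly
  13–15% of the 70+ population at the default cutoffs). **Every record
  draws a latent concentration; selection only decides whether it is
  revealed**, which makes selection conditionally independent of the
  biomarker given the modeled covariates — the exact premise under
  which inverse-probability weighting is consistent.
* Diagnosis (CU/MCI/dementia) depends on latent ADNC and age band;
  blood-sample non-donation depends on diagnosis (defaults 25.4%
  dementia, 8.6% MCI, 6.0% CU — the regime of outcome-dependent
  missingness the weighting corrects); the younger wave is selected by
  weighted sampling without replacement with inclusion odds 4:2:1 for
  dementia:MCI:CU (the dementia factor is a config knob, since active
  oversampling factors vary by design; MCI at twice the CU odds).
* `analytic_prevalence()` and `analytic_category_probs()` integrate the
  generative model by quadrature over the stratum age density and APOE
  distribution — the closed-form ground truth that recovery tests
  compare against, checked itself against a 400,000-draw Monte-Carlo
  estimate.

What the generator does **not** emulate: the joint covariate
distribution of any real population, assay noise and batch effects,
spectrum effects (age-dependent sensitivity/specificity of the
cutoffs), attrition over time, or household/geographic clustering.
Passing tests therefore demonstrate that the estimators recover the
truth *when the selection model is correctly specified and selection
depends only on modeled covariates* — they do not certify performance
under unmodeled informative selection.

## Numerical and design choices

* Age groups are half-open `[lower, upper)`: an exact 70th birthday
  belongs to `[70,75)`.
* Missing data conventions: empty cell (NA) for numerics, literal
  `"missing"` level for categoricals, tri-state yes/no/missing flags.
* Determinism: one master seed per generator call, split into one
  substream per covariate block, so changing one block's parameters
  does not perturb the other blocks' draws; imputation substreams per
  completed dataset.
* Problem sizes in the test suite were chosen so each recovery check
  has Monte-Carlo error well below its tolerance at desk scale:
  50,000 records for weighting recovery and rate checks, 200
  replicates of 2,500 for CI coverage, 5,000 points for breakpoint
  recovery, 20,000 for imputation recovery.
* Known limitations: the Wilson/$n_\mathrm{eff}$ interval treats
  weights as known (estimated-weight variability is ignored; in
  simulations this is conservative); no calibration to external
  population margins; no multiple-testing correction across
  comorbidity flags; no age-specific operating characteristics in the
  predictive-value sweep.

## One-command pipeline

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(
  simulation = sim_config(n_h4 = 10000, n_h3_frame = 12000,
                          n_h3_target = 2500),
  out_dir = "adncprev-run", seed = 1
)
res <- run_pipeline(cfg)
res$prevalence_age
```

`run_pipeline()` writes every table (cohort, weights, stage-model
summaries, prevalence by age/diagnosis, continuum staging, predictive
values, segmented fit, eligibility) plus a manifest to `out_dir`; runs
are byte-identical given the same config and seed. A thin command-line
wrapper ships at `inst/cli/adnc-pipeline.R`.
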