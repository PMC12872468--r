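# Synthetic cohort generator.
#
# Emulates the statistical structure the estimators assume: ADNC prevalence
# increasing in age and APOE e4 dose, a two-component log-normal pTau217
# mixture conditional on latent ADNC, cognitive diagnosis dependent on ADNC
# and age band, outcome-dependent blood-sample missingness (highest in
# dementia), and outcome-dependent nested selection of the younger wave.
# Every record carries a latent pTau217 concentration; participation and
# blood donation only decide whether it is revealed, so selection is
# conditionally independent of the biomarker given the modeled covariates
# and inverse-probability weighting is consistent by construction.

#' Simulation configuration
#'
#' Builds the configuration for [generate_cohort()]. Defaults encode the
#' study conditions the pipeline is designed for: blood-sample non-donation
#' of 25.4% (dementia), 8.6% (MCI) and 6.0% (cognitively unimpaired), a
#' younger-wave nested selection with inclusion odds 4:2:1 for
#' dementia:MCI:CU, and an ADNC log-odds model increasing in age and APOE
#' e4 count. All probabilities are checked to lie in `[0,1]`.
#'
#' @param n_h4 Number of invited 70+ individuals (the H4 frame).
#' @param n_h3_frame Size of the younger (58-69.9y) sampling frame.
#' @param n_h3_target Number selected from the younger frame into the
#'   substudy.
#' @param h4_age_rate Rate of the truncated-exponential age distribution on
#'   `[70, 105]` for the 70+ frame (per year).
#' @param adnc_model Named list: `intercept`, `age` (per year, age centered
#'   at 70) and `apoe` (per e4 allele), on the log-odds scale.
#' @param apoe_probs Probabilities of 0/1/2 e4 alleles (must sum to 1).
#' @param apoe_missing,edu_missing Missingness fractions for APOE genotype
#'   and education.
#' @param ptau_mixture List with `neg` and `pos` components, each
#'   `c(meanlog, sdlog)` of a log-normal in pg/ml.
#' @param diagnosis_model List with `dementia` and `mci` matrices (2 rows:
#'   ADNC absent/present; 6 columns: the canonical age groups) of
#'   conditional diagnosis probabilities; CU is the remainder.
#' @param blood_missingness Named per-diagnosis probabilities of *not*
#'   donating a blood sample, given participation.
#' @param participation_model Named list of log-odds terms for
#'   participation: `intercept`, `age` (per year from 70), `male`, and
#'   education offsets `edu_primary`, `edu_tertiary`, `edu_missing`
#'   (secondary is reference).
#' @param h3_selection_odds Named relative inclusion odds by subsequent
#'   cognitive diagnosis for the nested selection.
#' @param comorbidity_base Named baseline `P(flag = yes)` for each
#'   comorbidity flag.
#' @param comorbidity_adnc_log_or Named log odds ratios linking each flag to
#'   biomarker positivity (latent concentration at/above the upper cutoff);
#'   zero means independence.
#' @param flag_missing Missingness fraction for each tri-state flag.
#' @param seed Integer seed; fully determines the generated cohort.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_h4 = 10000L,
                       n_h3_frame = 12000L,
                       n_h3_target = 2500L,
                       h4_age_rate = 0.09,
                       adnc_model = list(intercept = -1.45, age = 0.085,
                                         apoe = 0.9),
                       apoe_probs = c("0" = 0.64, "1" = 0.32, "2" = 0.04),
                       apoe_missing = 0.03,
                       edu_missing = 0.04,
                       ptau_mixture = list(
                         neg = c(meanlog = log(0.25), sdlog = 0.35),
                         pos = c(meanlog = log(0.90), sdlog = 0.50)),
                       diagnosis_model = default_diagnosis_model(),
                       blood_missingness = c(dementia = 0.254, MCI = 0.086,
                                             CU = 0.06),
                       participation_model = list(intercept = 0.6,
                                                  age = -0.035, male = -0.2,
                                                  edu_primary = -0.3,
                                                  edu_tertiary = 0.25,
                                                  edu_missing = -0.5),
                       h3_selection_odds = c(dementia = 4, MCI = 2, CU = 1),
                       comorbidity_base = c(cardiovascular = 0.25,
                                            cerebrovascular = 0.08,
                                            copd = 0.08, diabetes = 0.12,
                                            cancer = 0.10, migraine = 0.08,
                                            psoriasis = 0.05,
                                            kidney_disease = 0.04,
                                            rheumatoid_arthritis = 0.05,
                                            gout = 0.04),
                       comorbidity_adnc_log_or = NULL,
                       flag_missing = 0.03,
                       seed = 1L) {
  if (is.null(comorbidity_adnc_log_or)) {
    comorbidity_adnc_log_or <- stats::setNames(
      rep(0, length(comorbidity_flags())), comorbidity_flags())
  }
  cfg <- structure(list(
    n_h4 = as.integer(n_h4), n_h3_frame = as.integer(n_h3_frame),
    n_h3_target = as.integer(n_h3_target), h4_age_rate = h4_age_rate,
    adnc_model = adnc_model, apoe_probs = apoe_probs,
    apoe_missing = apoe_missing, edu_missing = edu_missing,
    ptau_mixture = ptau_mixture, diagnosis_model = diagnosis_model,
    blood_missingness = blood_missingness,
    participation_model = participation_model,
    h3_selection_odds = h3_selection_odds,
    comorbidity_base = comorbidity_base,
    comorbidity_adnc_log_or = comorbidity_adnc_log_or,
    flag_missing = flag_missing, seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Default diagnosis model
#'
#' Conditional probabilities of dementia and MCI given latent ADNC status
#' (rows: absent, present) and age group (columns). Both rise with age and
#' with ADNC so that selection on diagnosis depletes biomarker positives.
#'
#' @return List with matrices `dementia` and `mci`.
#' @export
default_diagnosis_model <- function() {
  groups <- levels(assign_age_group(58))
  dementia <- rbind(
    absent  = c(0.01, 0.02, 0.04, 0.08, 0.14, 0.22),
    present = c(0.05, 0.10, 0.17, 0.28, 0.40, 0.52))
  mci <- rbind(
    absent  = c(0.06, 0.10, 0.13, 0.17, 0.22, 0.26),
    present = c(0.12, 0.18, 0.22, 0.25, 0.26, 0.25))
  colnames(dementia) <- colnames(mci) <- groups
  list(dementia = dementia, mci = mci)
}

validate_sim_config <- function(cfg) {
  chk_prob <- function(x, what) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
      stop("invalid config: ", what, " must lie in [0,1]", call. = FALSE)
    }
  }
  if (cfg$n_h4 < 0 || cfg$n_h3_frame < 0 || cfg$n_h3_target < 0 ||
      cfg$n_h3_target > cfg$n_h3_frame) {
    stop("invalid config: cohort sizes must be non-negative and ",
         "n_h3_target <= n_h3_frame", call. = FALSE)
  }
  if (cfg$h4_age_rate <= 0) {
    stop("invalid config: h4_age_rate must be positive", call. = FALSE)
  }
  if (abs(sum(cfg$apoe_probs) - 1) > 1e-8) {
    stop("invalid config: apoe_probs must sum to 1", call. = FALSE)
  }
  chk_prob(cfg$apoe_probs, "apoe_probs")
  chk_prob(c(cfg$apoe_missing, cfg$edu_missing, cfg$flag_missing),
           "missingness fractions")
  chk_prob(cfg$blood_missingness, "blood_missingness")
  if (!all(c("dementia", "MCI", "CU") %in% names(cfg$blood_missingness))) {
    stop("invalid config: blood_missingness needs dementia, MCI, CU",
         call. = FALSE)
  }
  for (comp in cfg$ptau_mixture) {
    if (comp[["sdlog"]] <= 0) {
      stop("invalid config: mixture sdlog must be positive", call. = FALSE)
    }
  }
  chk_prob(cfg$comorbidity_base, "comorbidity_base")
  dm <- cfg$diagnosis_model
  chk_prob(c(dm$dementia, dm$mci), "diagnosis_model")
  if (any(dm$dementia + dm$mci > 1)) {
    stop("invalid config: P(dementia) + P(MCI) must be <= 1 in every cell",
         call. = FALSE)
  }
  if (any(cfg$h3_selection_odds <= 0)) {
    stop("invalid config: h3_selection_odds must be positive", call. = FALSE)
  }
  invisible(cfg)
}

# Truncated-exponential ages on [70, 105] via inverse CDF.
.r_h4_age <- function(n, rate) {
  u <- stats::runif(n)
  70 + (-log(1 - u * (1 - exp(-rate * 35))) / rate)
}

.adnc_logit <- function(cfg, age, apoe_count) {
  m <- cfg$adnc_model
  m$intercept + m$age * (age - 70) + m$apoe * apoe_count
}

#' Generate a synthetic cohort
#'
#' Draws a full two-wave cohort (70+ frame plus the younger sampling frame)
#' with latent ADNC, latent pTau217 revealed only for observed blood
#' samples, diagnosis-dependent blood-sample missingness and an
#' outcome-dependent nested selection of the younger wave. The returned
#' ground truth carries the latent indicators and the exact per-record
#' selection probabilities; it is consumed only by tests and never by the
#' estimation stages.
#'
#' @param config A [sim_config()].
#' @return List of class `adnc_sim` with elements `cohort` (a validated
#'   cohort data frame) and `truth` (data frame: `id`, `adnc_true`,
#'   `ptau_latent`, `positive_true`, `p_participate`, `p_blood`,
#'   `p_select`).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  # one sub-stream seed per covariate block, split from the master seed
  block_seed <- sample.int(.Machine$integer.max, 12L)

  n <- config$n_h4 + config$n_h3_frame
  wave <- rep(c("H4", "H3"), c(config$n_h4, config$n_h3_frame))

  set.seed(block_seed[1L])
  age <- c(.r_h4_age(config$n_h4, config$h4_age_rate),
           stats::runif(config$n_h3_frame, 58, 70))
  sex <- sample(c("female", "male"), n, replace = TRUE,
                prob = c(0.53, 0.47))

  set.seed(block_seed[2L])
  education <- sample(c("primary", "secondary", "tertiary"), n,
                      replace = TRUE, prob = c(0.35, 0.45, 0.20))
  education[stats::runif(n) < config$edu_missing] <- "missing"

  set.seed(block_seed[3L])
  apoe_num <- sample(0:2, n, replace = TRUE, prob = config$apoe_probs)
  apoe <- as.character(apoe_num)
  apoe[stats::runif(n) < config$apoe_missing] <- "missing"

  set.seed(block_seed[4L])
  adnc <- stats::rbinom(n, 1L, stats::plogis(.adnc_logit(config, age,
                                                         apoe_num)))

  set.seed(block_seed[5L])
  mix <- config$ptau_mixture
  ptau_latent <- ifelse(
    adnc == 1L,
    stats::rlnorm(n, mix$pos[["meanlog"]], mix$pos[["sdlog"]]),
    stats::rlnorm(n, mix$neg[["meanlog"]], mix$neg[["sdlog"]]))
  positive_true <- as.integer(ptau_latent >= cutoff_scheme()$upper)

  set.seed(block_seed[6L])
  grp <- as.character(assign_age_group(age))
  dm <- config$diagnosis_model
  row <- ifelse(adnc == 1L, "present", "absent")
  p_dem <- dm$dementia[cbind(row, grp)]
  p_mci <- dm$mci[cbind(row, grp)]
  u <- stats::runif(n)
  diagnosis <- ifelse(u < p_dem, "dementia",
                      ifelse(u < p_dem + p_mci, "MCI", "CU"))
  severity <- rep("not_applicable", n)
  dem <- diagnosis == "dementia"
  severity[dem] <- sample(c("mild", "moderate", "severe"), sum(dem),
                          replace = TRUE, prob = c(0.55, 0.30, 0.15))

  set.seed(block_seed[7L])
  pm <- config$participation_model
  edu_eff <- c(primary = pm$edu_primary, secondary = 0,
               tertiary = pm$edu_tertiary, missing = pm$edu_missing)
  p_part <- stats::plogis(pm$intercept + pm$age * (age - 70) +
                            pm$male * (sex == "male") + edu_eff[education])
  participated <- stats::runif(n) < p_part

  set.seed(block_seed[8L])
  p_blood_given_part <- 1 - config$blood_missingness[diagnosis]
  gave_blood <- participated & (stats::runif(n) < p_blood_given_part)
  p_blood <- unname(p_blood_given_part)

  set.seed(block_seed[9L])
  selected <- rep(FALSE, n)
  p_select <- rep(NA_real_, n)
  h3_pool <- which(wave == "H3" & gave_blood)
  if (config$n_h3_target > 0L && length(h3_pool)) {
    odds <- config$h3_selection_odds[diagnosis[h3_pool]]
    odds[is.na(odds)] <- 1
    k <- min(config$n_h3_target, length(h3_pool))
    pick <- sample(h3_pool, k, prob = odds)
    selected[pick] <- TRUE
    # true inclusion probability is constant within diagnosis class
    # (exchangeability under weighted sampling); recover it empirically
    # from the pool for the ground-truth record
    sel_rate <- tapply(selected[h3_pool], diagnosis[h3_pool], mean)
    p_select[h3_pool] <- sel_rate[diagnosis[h3_pool]]
  }

  set.seed(block_seed[10L])
  creatinine <- stats::rlnorm(n, log(0.85) + 0.12 * (sex == "male"), 0.18)
  creatinine[stats::runif(n) < 0.02] <- NA
  bmi <- stats::rnorm(n, 26, 4)
  bmi[stats::runif(n) < 0.08] <- NA

  set.seed(block_seed[11L])
  stroke <- ifelse(stats::runif(n) < 0.07, "yes", "no")
  stroke[stats::runif(n) < 0.05] <- "missing"
  flags <- matrix(NA_character_, n, length(comorbidity_flags()),
                  dimnames = list(NULL, comorbidity_flags()))
  for (fl in comorbidity_flags()) {
    base <- config$comorbidity_base[[fl]]
    lor <- config$comorbidity_adnc_log_or[[fl]]
    p_fl <- stats::plogis(stats::qlogis(base) + lor * positive_true)
    flags[, fl] <- ifelse(stats::runif(n) < p_fl, "yes", "no")
    flags[stats::runif(n) < config$flag_missing, fl] <- "missing"
  }

  # observation rule: the biomarker is revealed only for analysable samples
  observed <- (wave == "H4" & gave_blood) | (wave == "H3" & selected)
  ptau217 <- ifelse(observed, ptau_latent, NA_real_)

  # younger-wave records without a later assessment have no diagnosis
  h3_unassessed <- wave == "H3" & !participated
  diagnosis[h3_unassessed] <- "undetermined"
  severity[h3_unassessed] <- "not_applicable"

  cohort <- data.frame(
    id = sprintf("P%06d", seq_len(n)), cohort_wave = wave, age = age,
    sex = sex, education = education, apoe_e4_count = apoe,
    cognitive_status = diagnosis, dementia_severity = severity,
    ptau217 = ptau217, creatinine = creatinine, bmi = bmi,
    stroke_history = stroke, as.data.frame(flags),
    participated = participated, gave_blood = gave_blood,
    selected_into_substudy = selected, stringsAsFactors = FALSE)
  validate_cohort(cohort)

  truth <- data.frame(
    id = cohort$id, adnc_true = adnc, ptau_latent = ptau_latent,
    positive_true = positive_true, p_participate = unname(p_part),
    p_blood = p_blood, p_select = unname(p_select),
    stringsAsFactors = FALSE)

  structure(list(cohort = cohort, truth = truth, config = config),
            class = "adnc_sim")
}

#' Analysis subset of a cohort
#'
#' The records whose plasma pTau217 measurement is observed: 70+
#' blood donors plus the selected younger substudy.
#'
#' @param cohort Cohort data frame.
#' @return Logical vector marking analysable rows.
#' @export
analysis_rows <- function(cohort) {
  (cohort$cohort_wave == "H4" & cohort$gave_blood) |
    (cohort$cohort_wave == "H3" & cohort$selected_into_substudy)
}

.age_density <- function(config, lo, hi) {
  # mixture of the two wave age distributions restricted to [lo, hi)
  rate <- config$h4_age_rate
  n_tot <- config$n_h4 + config$n_h3_frame
  w_h3 <- config$n_h3_frame / n_tot
  w_h4 <- config$n_h4 / n_tot
  z <- 1 - exp(-rate * 35)
  f <- function(a) {
    d <- numeric(length(a))
    in_h3 <- a >= 58 & a < 70
    in_h4 <- a >= 70 & a <= 105
    d[in_h3] <- w_h3 / 12
    d[in_h4] <- d[in_h4] + w_h4 * rate * exp(-rate * (a[in_h4] - 70)) / z
    d
  }
  mass <- stats::integrate(f, lo, min(hi, 105))$value
  if (mass <= 0) stop("empty stratum support", call. = FALSE)
  list(f = f, mass = mass, hi = min(hi, 105))
}

#' Analytic ADNC prevalence in an age stratum
#'
#' Closed-form (quadrature) prevalence implied by the generative model:
#' the ADNC logit model integrated over the stratum's age density and the
#' APOE e4 allele-count distribution. Used as ground truth in recovery
#' tests.
#'
#' @param config A [sim_config()].
#' @param lower,upper Stratum bounds in years (half-open interval).
#' @return Prevalence in `[0,1]`.
#' @export
analytic_prevalence <- function(config, lower = 70, upper = Inf) {
  validate_sim_config(config)
  if (lower >= 105 || upper <= 58) stop("empty stratum support",
                                        call. = FALSE)
  dens <- .age_density(config, max(lower, 58), upper)
  total <- 0
  for (k in 0:2) {
    pk <- config$apoe_probs[[as.character(k)]]
    if (pk == 0) next
    g <- function(a) {
      stats::plogis(.adnc_logit(config, a, k)) * dens$f(a)
    }
    total <- total + pk *
      stats::integrate(g, max(lower, 58), dens$hi)$value
  }
  total / dens$mass
}

#' Analytic biomarker-category probabilities in an age stratum
#'
#' Probability that the latent pTau217 concentration falls in each
#' two-cutoff category, implied by the generative mixture and the analytic
#' ADNC prevalence. The `positive` entry is the population prevalence of
#' biomarker positivity that a consistent weighted estimator should
#' recover.
#'
#' @inheritParams analytic_prevalence
#' @param scheme A [cutoff_scheme()].
#' @return Named numeric vector over `negative`, `intermediate`,
#'   `positive` (sums to 1).
#' @export
analytic_category_probs <- function(config, lower = 70, upper = Inf,
                                    scheme = cutoff_scheme()) {
  p <- analytic_prevalence(config, lower, upper)
  mix <- config$ptau_mixture
  cat_probs <- function(comp) {
    lo <- stats::plnorm(scheme$lower, comp[["meanlog"]], comp[["sdlog"]])
    hi <- stats::plnorm(scheme$upper, comp[["meanlog"]], comp[["sdlog"]])
    c(negative = lo, intermediate = hi - lo, positive = 1 - hi)
  }
  p * cat_probs(mix$pos) + (1 - p) * cat_probs(mix$neg)
}
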