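# Shared fixtures: small simulated cohorts built in code.

small_sim <- function(seed = 42L, ...) {
  sim_config(n_h4 = 1500L, n_h3_frame = 1800L, n_h3_target = 400L,
             seed = seed, ...)
}

# a 70+-only configuration (no nested younger wave)
h4_only_sim <- function(n = 5000L, seed = 42L, ...) {
  sim_config(n_h4 = n, n_h3_frame = 0L, n_h3_target = 0L, seed = seed, ...)
}

# a configuration with no selection effects at all: everyone participates,
# donates blood, and the younger wave is not sampled
no_selection_sim <- function(n = 20000L, seed = 42L) {
  sim_config(n_h4 = n, n_h3_frame = 0L, n_h3_target = 0L,
             blood_missingness = c(dementia = 0, MCI = 0, CU = 0),
             participation_model = list(intercept = 20, age = 0, male = 0,
                                        edu_primary = 0, edu_tertiary = 0,
                                        edu_missing = 0),
             seed = seed)
}

# estimated, trimmed inverse-probability weights for a generated cohort
fit_trimmed_weights <- function(cohort) {
  specs <- default_stage_specs()
  if (!any(cohort$cohort_wave == "H3" & cohort$selected_into_substudy)) {
    specs$h3_nested_selection <- NULL
  }
  fits <- suppressWarnings(
    lapply(specs, function(s) fit_stage_probability(cohort, s)))
  trim_weights(compose_weights(cohort, fits))
}

# hand-rolled cohort of valid records for constructor-level tests
toy_cohort <- function(n = 6L) {
  flags <- as.data.frame(
    matrix("no", n, length(comorbidity_flags()),
           dimnames = list(NULL, comorbidity_flags())))
  data.frame(
    id = sprintf("T%03d", seq_len(n)),
    cohort_wave = rep(c("H4", "H3"), length.out = n),
    age = rep(c(72.5, 60.1), length.out = n),
    sex = rep(c("female", "male"), length.out = n),
    education = "secondary",
    apoe_e4_count = "0",
    cognitive_status = "CU",
    dementia_severity = "not_applicable",
    ptau217 = seq(0.2, by = 0.15, length.out = n),
    creatinine = 0.9,
    bmi = 26,
    stroke_history = "no",
    flags,
    participated = TRUE,
    gave_blood = TRUE,
    selected_into_substudy = rep(c(FALSE, TRUE), length.out = n),
    stringsAsFactors = FALSE)
}
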