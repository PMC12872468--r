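elig_cohort <- function() {
  co <- toy_cohort(6)
  co$cohort_wave <- "H4"
  co$age <- 75
  co$cognitive_status <- c("MCI", "dementia", "MCI", "dementia", "CU",
                           "MCI")
  co$dementia_severity <- c("not_applicable", "mild", "not_applicable",
                            "severe", "not_applicable", "not_applicable")
  co$ptau217 <- c(0.70, 0.70, 0.50, 0.70, 0.70, 0.70)
  co$stroke_history <- c("no", "no", "no", "no", "no", "yes")
  co$selected_into_substudy <- FALSE
  co
}

test_that("eligibility requires early symptomatic diagnosis, positivity and no exclusion", {
  co <- elig_cohort()
  got <- assess_eligibility(co)
  # MCI+positive eligible; mild dementia eligible; intermediate pTau not;
  # severe dementia not; CU not; stroke history excludes
  expect_identical(got, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))

  # BMI bounds apply when configured
  co$bmi <- c(26, 40, 26, 26, 26, 26)
  crit <- eligibility_criteria(bmi_bounds = c(17, 35))
  expect_identical(assess_eligibility(co, crit),
                   c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))

  co$stroke_history[1] <- "missing"
  expect_error(assess_eligibility(co), "impute before")
})

test_that("imputation leaves observed cells untouched and fully observed data unchanged", {
  sim <- generate_cohort(small_sim(seed = 61L))
  co <- sim$cohort[analysis_rows(sim$cohort), ]
  plan <- imputation_plan(m = 5L, seed = 3L)
  done <- impute_missing(co, plan)
  expect_length(done, 5L)
  mask <- attr(done, "missing_mask")
  for (d in done) {
    # no missing cells remain in plan variables
    expect_false(any(is.na(d$bmi)))
    expect_false(any(d$apoe_e4_count == "missing"))
    expect_false(any(d$stroke_history == "missing"))
    # observed cells are byte-identical
    expect_identical(d$bmi[!mask[, "bmi"]], co$bmi[!mask[, "bmi"]])
    expect_identical(d$apoe_e4_count[!mask[, "apoe_e4_count"]],
                     co$apoe_e4_count[!mask[, "apoe_e4_count"]])
    expect_identical(d$stroke_history[!mask[, "stroke_history"]],
                     co$stroke_history[!mask[, "stroke_history"]])
  }
  # distinct substreams: the m completions differ on imputed cells
  expect_false(identical(done[[1]]$bmi, done[[2]]$bmi))

  # a fully observed cohort passes through unchanged
  full <- co
  full$bmi[is.na(full$bmi)] <- 25
  full$apoe_e4_count[full$apoe_e4_count == "missing"] <- "0"
  full$stroke_history[full$stroke_history == "missing"] <- "no"
  done2 <- impute_missing(full, plan)
  for (d in done2) expect_identical(d, full)

  bad <- co
  bad$bmi <- NA_real_
  expect_error(impute_missing(bad, plan), "entirely missing")
})

test_that("MCAR-deleted binary prevalence is recovered by the chained imputer", {
  set.seed(71)
  n <- 20000L
  age <- runif(n, 70, 95)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  # stroke depends on the observed covariates; marginal prevalence 0.4
  p <- plogis(-0.405 + 0.01 * (age - 82.5) - 0.02 * (sex == "male"))
  stroke_full <- ifelse(runif(n) < p, "yes", "no")
  truth <- mean(stroke_full == "yes")
  co <- toy_cohort(6)[rep(1, n), ]
  co$id <- as.character(seq_len(n))
  co$cohort_wave <- "H4"; co$age <- age; co$sex <- sex
  co$stroke_history <- stroke_full
  miss <- runif(n) < 0.30  # MCAR
  co$stroke_history[miss] <- "missing"
  rownames(co) <- NULL

  done <- impute_missing(co, imputation_plan(variables = "stroke_history",
                                             m = 5L, iterations = 3L,
                                             seed = 9L))
  pooled <- mean(vapply(done, function(d) mean(d$stroke_history == "yes"),
                        numeric(1)))
  mc_se <- sqrt(truth * (1 - truth) / sum(miss))
  expect_lt(abs(pooled - truth), 3 * mc_se)
})

test_that("weighted eligible proportion pools imputations and respects invariances", {
  co <- elig_cohort()
  # nobody positive -> 0
  co0 <- co; co0$ptau217 <- 0.2
  expect_equal(
    eligible_proportion(co0, rep(1, 6), plan = NULL)$proportion, 0)

  # unit weights, fully observed -> simple fraction
  est <- eligible_proportion(co, rep(1, 6), plan = NULL)
  expect_equal(est$proportion, 2 / 6)

  # invariant to weight rescaling
  w <- c(1, 2, 3, 4, 5, 6)
  e1 <- eligible_proportion(co, w, plan = NULL)
  e2 <- eligible_proportion(co, 10 * w, plan = NULL)
  expect_equal(e1$proportion, e2$proportion)

  # pooled estimate lies within the per-imputation envelope
  sim <- generate_cohort(small_sim(seed = 67L))
  obs <- sim$cohort[analysis_rows(sim$cohort), ]
  h4 <- obs[obs$cohort_wave == "H4", ]
  est3 <- eligible_proportion(h4, rep(1, nrow(h4)),
                              plan = imputation_plan(m = 4L, seed = 2L))
  expect_true(est3$min_imputation <= est3$proportion &
                est3$proportion <= est3$max_imputation)
})

test_that("weighting corrects the eligible-fraction bias induced by selection", {
  # generative truth from a large no-selection cohort (everyone observed)
  cfg0 <- no_selection_sim(n = 60000L, seed = 83L)
  sim0 <- generate_cohort(cfg0)
  co0 <- sim0$cohort
  co0$stroke_history[co0$stroke_history == "missing"] <- "no"
  truth <- mean(assess_eligibility(co0))

  # same generative model under dementia-depleting selection
  cfg1 <- h4_only_sim(n = 30000L, seed = 89L)
  sim1 <- generate_cohort(cfg1)
  ws <- fit_trimmed_weights(sim1$cohort)
  obs <- sim1$cohort[analysis_rows(sim1$cohort), ]
  est <- eligible_proportion(obs, ws, plan = imputation_plan(m = 3L,
                                                             seed = 7L))
  se <- sqrt(truth * (1 - truth) / est$n_eff)
  expect_lt(abs(est$proportion - truth), 3 * se + 0.005)

  # the unweighted estimate is biased low (eligible are depleted)
  unw <- eligible_proportion(obs, rep(1, nrow(obs)),
                             plan = imputation_plan(m = 3L, seed = 7L))
  expect_lt(unw$proportion, est$proportion)
})
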