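test_that("stage logistic model recovers known generating coefficients", {
  set.seed(21)
  n <- 20000L
  age <- runif(n, 70, 95)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  eta <- 3 - 0.05 * (age - 70) - 0.4 * (sex == "male")
  toy <- data.frame(id = as.character(seq_len(n)), age = age, sex = sex,
                    participated = runif(n) < plogis(eta),
                    stringsAsFactors = FALSE)
  spec <- stage_model_spec("participation_h4", "participated",
                           c("age", "sex"))
  fit <- fit_stage_probability(toy, spec)
  expect_identical(fit$method, "ml")
  expect_length(fit$probabilities, n)
  # compare against generating truth at 3 Wald SEs
  ref <- glm(participated ~ age + sex, data = toy, family = binomial())
  se <- summary(ref)$coefficients[, "Std. Error"]
  truth <- c(3 + 0.05 * 70, -0.05, -0.4)
  expect_true(all(abs(fit$coefficients - truth) < 3 * se))
})

test_that("constant outcomes degrade gracefully and missing levels are retained", {
  co <- toy_cohort(8)
  spec <- stage_model_spec("participation_h4", "participated",
                           c("age", "sex"))
  expect_warning(fit <- fit_stage_probability(co, spec), "degenerate")
  expect_identical(fit$method, "degenerate")
  expect_true(all(fit$probabilities > 0.99))

  # explicit "missing" APOE level enters the design and the fit succeeds
  sim <- generate_cohort(small_sim(seed = 5L))
  co2 <- sim$cohort
  expect_gt(sum(co2$apoe_e4_count == "missing"), 0)
  fit2 <- fit_stage_probability(
    co2, stage_model_spec("blood_donation_h4", "gave_blood",
                          c("age", "sex", "apoe_e4_count"),
                          risk_set = "participated"))
  expect_identical(fit2$method, "ml")
  expect_true(any(grepl("missing", names(fit2$coefficients))))
  expect_length(fit2$probabilities, sum(co2$participated))
})

test_that("complete separation triggers the ridge fallback, not silent failure", {
  set.seed(9)
  n <- 200L
  x <- sample(c("yes", "no"), n, replace = TRUE)
  toy <- data.frame(id = as.character(seq_len(n)), flag = x,
                    picked = x == "yes", age = runif(n, 70, 90),
                    stringsAsFactors = FALSE)
  spec <- stage_model_spec("h3_nested_selection", "picked",
                           c("flag", "age"))
  expect_warning(fit <- fit_stage_probability(toy, spec), "ridge")
  expect_identical(fit$method, "ridge")
  expect_true(all(fit$probabilities > 0 & fit$probabilities < 1))
})

test_that("weights compose as inverse products per wave", {
  co <- toy_cohort(3)
  co$cohort_wave <- c("H4", "H3", "H4")
  co$age <- c(72, 60, 75)
  co$selected_into_substudy <- c(FALSE, TRUE, FALSE)
  mk_fit <- function(stage, p) {
    structure(list(stage = stage,
                   probabilities = setNames(p, co$id),
                   risk_set = rep(TRUE, 3), coefficients = NULL,
                   converged = TRUE, method = "ml"),
              class = "stage_fit")
  }
  fits <- list(
    participation_h4 = mk_fit("participation_h4", c(0.5, 0.5, 1)),
    blood_donation_h4 = mk_fit("blood_donation_h4", c(0.5, 0.5, 1)),
    h3_nested_selection = mk_fit("h3_nested_selection", c(NA, 0.5, NA)))
  ws <- compose_weights(co, fits)
  expect_equal(ws$weights$raw_weight, c(4, 8, 1))

  # all probabilities one -> unit weights -> weighted equals unweighted
  fits1 <- list(
    participation_h4 = mk_fit("participation_h4", rep(1 - 1e-15, 3)),
    blood_donation_h4 = mk_fit("blood_donation_h4", rep(1 - 1e-15, 3)),
    h3_nested_selection = mk_fit("h3_nested_selection", rep(1 - 1e-15, 3)))
  w1 <- compose_weights(co, fits1)$weights$weight
  ind <- c(1, 0, 1)
  expect_equal(sum(w1 * ind) / sum(w1), mean(ind))

  # a missing stage probability is an error naming record and stage
  fits$blood_donation_h4$probabilities["T002"] <- NA
  expect_error(compose_weights(co, fits), "blood_donation_h4.*T002")
  expect_error(compose_weights(co, fits[c(1, 3)]), "missing stage fit")
})

test_that("trimming winsorizes at median +/- 3 IQR with interpolated quartiles", {
  # degenerate IQR: median 1, IQR 0 -> every weight collapses to 1
  ws <- trim_weights(weight_set(c(1, 1, 1, 1, 100)))
  expect_equal(ws$weights$weight, rep(1, 5))
  expect_equal(unname(ws$bounds), c(1, 1))

  # interpolated quartiles: median 3, Q1 2, Q3 4 -> bounds [eps, 9]
  ws2 <- trim_weights(weight_set(c(1, 2, 3, 4, 50)))
  expect_equal(ws2$weights$weight, c(1, 2, 3, 4, 9))
  expect_equal(unname(ws2$bounds["upper"]), 9)
  expect_gt(ws2$bounds["lower"], 0)  # negative lower bound floored

  # identical weights unchanged; ordering preserved except ties at bounds
  ws3 <- trim_weights(weight_set(rep(2.5, 4)))
  expect_equal(ws3$weights$weight, rep(2.5, 4))
  raw <- c(0.2, 1, 1.5, 2, 2.2, 30)
  tr <- trim_weights(weight_set(raw))$weights$weight
  expect_true(all(diff(tr[order(raw)]) >= 0))
  expect_true(all(tr >= tr[1] - 1e-12))

  expect_error(trim_weights(weight_set(5)), "at least 2")
})

test_that("estimated weights correct dementia-depleting selection end to end", {
  cfg <- h4_only_sim(n = 30000L, seed = 31L)
  sim <- generate_cohort(cfg)
  co <- sim$cohort
  ws <- fit_trimmed_weights(co)
  obs <- co[analysis_rows(co), ]
  status <- classify_adnc(obs$ptau217)
  w <- ws$weights$weight
  truth <- analytic_category_probs(cfg, 70, Inf)[["positive"]]
  p_w <- sum(w * (status == "positive")) / sum(w)
  p_u <- mean(status == "positive")
  se <- sqrt(truth * (1 - truth) / kish_neff(w))
  expect_lt(abs(p_w - truth), 3 * se)
  expect_lt(p_u, truth)        # selection depletes positives
  expect_lt(p_u + 2 * se, p_w) # and weighting moves the estimate up
})
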