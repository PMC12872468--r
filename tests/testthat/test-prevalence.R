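test_that("weighted proportions reduce to arithmetic on simple inputs", {
  # uniform weights equal the plain sample proportion exactly
  x <- c(1, 0, 1, 1, 0)
  est <- weighted_proportion(x, rep(2, 5))
  expect_identical(est$proportion, mean(x))
  expect_identical(est$n_eff, 5)

  # weights {2,1} on indicators {1,0} -> 2/3
  expect_equal(weighted_proportion(c(1, 0), c(2, 1))$proportion, 2 / 3)

  expect_error(weighted_proportion(numeric(0), numeric(0)), "empty")
  expect_error(weighted_proportion(c(1, 0), c(0, 0)), "all weights are zero")

  # CI respects [0,1] and contains the point estimate
  est2 <- weighted_proportion(c(rep(1, 19), 0), runif(20, 0.5, 2))
  expect_true(est2$ci_lower <= est2$proportion &
                est2$proportion <= est2$ci_upper)
  expect_true(est2$ci_lower >= 0 && est2$ci_upper <= 1)

  # bootstrap option produces a sane interval too
  set.seed(4)
  est3 <- weighted_proportion(rbinom(200, 1, 0.3), runif(200, 0.5, 2),
                              ci_method = "bootstrap", boot_reps = 200)
  expect_true(est3$ci_lower <= est3$proportion &
                est3$proportion <= est3$ci_upper)
})

test_that("prevalence tables partition strata and carry exact marginals", {
  sim <- generate_cohort(small_sim(seed = 17L))
  co <- sim$cohort[analysis_rows(sim$cohort), ]
  w <- runif(nrow(co), 0.5, 4)
  status <- classify_adnc(co$ptau217)
  tab <- prevalence_table(co, w, status, "age_group")

  # category proportions sum to 1 within each stratum
  sums <- tapply(tab$proportion, tab$age_group, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # the marginal row equals the weight-weighted average of stratum rows
  for (lev in adnc_levels()) {
    strata <- tab[tab$age_group != "overall" & tab$category == lev, ]
    overall <- tab[tab$age_group == "overall" & tab$category == lev, ]
    stratum_wsum <- tapply(
      tab$n_weighted[tab$age_group != "overall"],
      tab$age_group[tab$age_group != "overall"], sum)
    stratum_wsum <- stratum_wsum[!is.na(stratum_wsum) & stratum_wsum > 0]
    agg <- sum(strata$proportion[match(names(stratum_wsum),
                                       strata$age_group)] * stratum_wsum) /
      sum(stratum_wsum)
    expect_equal(overall$proportion, agg, tolerance = 1e-12)
  }

  # unit weights reproduce the unweighted proportions exactly
  tab1 <- prevalence_table(co, rep(1, nrow(co)), status, "age_group")
  grp <- assign_age_group(co$age)
  for (g in levels(grp)) {
    if (!any(grp == g)) next
    expect_equal(
      tab1$proportion[tab1$age_group == g & tab1$category == "positive"],
      mean(status[grp == g] == "positive"))
  }

  # single stratum table equals weighted_proportion output
  one <- co[grp == "[70,75)", ]
  w_one <- w[grp == "[70,75)"]
  t_one <- prevalence_table(one, w_one, classify_adnc(one$ptau217),
                            "age_group")
  direct <- weighted_proportion(classify_adnc(one$ptau217) == "positive",
                                w_one)
  expect_equal(
    t_one$proportion[t_one$age_group == "[70,75)" &
                       t_one$category == "positive"],
    direct$proportion)

  # empty strata are emitted with zero counts, not dropped
  expect_true(all(
    t_one$n[t_one$age_group %in% c("[80,85)", "[90,Inf)")] == 0))
})

test_that("the weighted chi-squared test reduces to Pearson and detects association", {
  # identical group proportions -> statistic 0
  g <- rep(c("a", "b"), each = 20)
  cat2 <- rep(rep(c("x", "y"), each = 10), 2)
  t0 <- proportion_test(g, cat2)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)

  # hand-computed Pearson value for the 2x2 table {{30,10},{10,30}}
  g2 <- rep(c("a", "b"), each = 40)
  c2 <- c(rep("x", 30), rep("y", 10), rep("x", 10), rep("y", 30))
  t2 <- proportion_test(g2, c2)
  tab <- table(g2, c2)
  hand <- sum((tab - outer(rowSums(tab), colSums(tab)) / sum(tab))^2 /
                (outer(rowSums(tab), colSums(tab)) / sum(tab)))
  expect_equal(t2$statistic, hand)
  expect_equal(t2$statistic, 20)  # 4 cells * (10^2 / 20)
  expect_identical(t2$df, 1L)
  expect_equal(t2$statistic,
               unname(chisq.test(tab, correct = FALSE)$statistic))

  # unit weights leave the statistic unchanged; small cells warn in-band
  t2w <- proportion_test(g2, c2, rep(1, 80))
  expect_equal(t2w$statistic, t2$statistic)
  expect_error(proportion_test(rep("a", 10), rep(c("x", "y"), 5)),
               "at least 2 groups")
})

test_that("comorbidity association recovers a known conditional odds ratio", {
  lor <- stats::setNames(rep(0, length(comorbidity_flags())),
                         comorbidity_flags())
  lor["diabetes"] <- log(2)
  cfg <- h4_only_sim(n = 50000L, seed = 23L, comorbidity_adnc_log_or = lor)
  sim <- generate_cohort(cfg)
  co <- sim$cohort[analysis_rows(sim$cohort), ]
  ws <- fit_trimmed_weights(sim$cohort)
  est <- comorbidity_association(co, ws, "diabetes")
  se_log <- (log(est$ci_upper) - log(est$ci_lower)) / (2 * qnorm(0.975))
  expect_lt(abs(log(est$odds_ratio) - log(2)), 3 * se_log)

  # a flag generated independently of the biomarker stays near OR 1
  est0 <- comorbidity_association(co, ws, "gout")
  expect_lt(abs(log(est0$odds_ratio)), 3 *
              (log(est0$ci_upper) - log(est0$ci_lower)) / (2 * qnorm(0.975)))

  expect_error(comorbidity_association(co, ws, "not_a_flag"), "unknown")
})

test_that("a flag identical to the outcome triggers the ridge fallback", {
  sim <- generate_cohort(small_sim(seed = 29L))
  co <- sim$cohort[analysis_rows(sim$cohort), ]
  status <- classify_adnc(co$ptau217)
  co$diabetes <- ifelse(status == "positive", "yes", "no")
  expect_warning(
    est <- comorbidity_association(co, rep(1, nrow(co)), "diabetes"),
    "separated|ridge")
  expect_identical(est$method, "ridge")
  expect_gt(est$odds_ratio, 1)
})
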