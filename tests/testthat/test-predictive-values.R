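test_that("Bayes identities hold: an uninformative test returns the prevalence", {
  # se + sp = 1 -> PPV = prev and NPV = 1 - prev, over a prevalence grid
  prevs <- seq(0.05, 0.95, by = 0.05)
  for (se in c(0.3, 0.5, 0.7)) {
    expect_equal(ppv(se, 1 - se, prevs), prevs, tolerance = 1e-12)
    expect_equal(npv(se, 1 - se, prevs), 1 - prevs, tolerance = 1e-12)
  }
  # perfect test
  expect_identical(ppv(1, 1, 0.5), 1)
  expect_identical(npv(1, 1, 0.5), 1)
  # direct formula evaluation
  expect_equal(ppv(0.916, 0.8655, 0.334),
               0.916 * 0.334 / (0.916 * 0.334 + (1 - 0.8655) * (1 - 0.334)))
  expect_equal(npv(0.916, 0.8655, 0.652),
               0.8655 * 0.348 / ((1 - 0.916) * 0.652 + 0.8655 * 0.348))
  expect_error(ppv(0, 1, 0.5), "denominator")
  expect_error(npv(1.2, 0.9, 0.5), "\\[0,1\\]")
})

test_that("predictive values are monotone in se, sp and prevalence", {
  set.seed(8)
  for (i in 1:50) {
    se <- runif(1, 0.05, 0.95); sp <- runif(1, 0.05, 0.95)
    p <- runif(1, 0.05, 0.95); d <- runif(1, 0.01, 0.04)
    expect_gte(ppv(se + d, sp, p), ppv(se, sp, p))
    expect_gte(ppv(se, sp + d, p), ppv(se, sp, p))
    expect_gte(ppv(se, sp, p + d), ppv(se, sp, p))
    expect_gte(npv(se + d, sp, p), npv(se, sp, p))
    expect_gte(npv(se, sp + d, p), npv(se, sp, p))
    expect_lte(npv(se, sp, p + d), npv(se, sp, p))
  }
})

test_that("shrinkage is an affine, order-preserving contraction toward 0.5", {
  expect_identical(shrink_toward_chance(0.5, 0.9), 0.5)  # fixed point
  expect_equal(shrink_toward_chance(1.0, 0.9), 0.95)
  expect_equal(shrink_toward_chance(0.916, 0.9), 0.8744)
  x <- seq(0, 1, by = 0.1)
  expect_identical(shrink_toward_chance(x, 1), x)
  y <- shrink_toward_chance(x, 0.7)
  expect_true(all(diff(y) > 0))
  expect_true(all(abs(y - 0.5) <= abs(x - 0.5)))
  expect_error(shrink_toward_chance(0.9, 0))
})

test_that("the default diagnostic grid enumerates 133 x 242 closed-range points", {
  g <- diagnostic_grid()
  expect_length(g$se, 133L)
  expect_length(g$sp, 242L)
  expect_equal(range(g$se), c(0.850, 0.982), tolerance = 1e-12)
  expect_equal(range(g$sp), c(0.745, 0.986), tolerance = 1e-12)
  # index construction avoids floating drift: all multiples of the step
  expect_true(all(abs(g$se * 1000 - round(g$se * 1000)) < 1e-9))
})

test_that("grid summaries match a brute-force enumeration oracle", {
  # degenerate grid: summary collapses to the point evaluation
  g1 <- diagnostic_grid(0.9, 0.9, 0.8, 0.8)
  s1 <- grid_summary(0.334, g1)
  expect_equal(s1$median, s1$p2.5)
  expect_equal(s1$median, s1$p97.5)
  expect_equal(s1$median[s1$measure == "ppv"], ppv(0.9, 0.8, 0.334))

  # small grid: explicit double loop, manual median of the value list
  g2 <- diagnostic_grid(0.85, 0.86, 0.745, 0.76)
  vals <- c()
  for (se in seq(0.85, 0.86, by = 0.001)) {
    for (sp in seq(0.745, 0.76, by = 0.001)) {
      vals <- c(vals, se * 0.3 / (se * 0.3 + (1 - sp) * 0.7))
    }
  }
  vs <- sort(vals)
  n <- length(vs)
  manual_median <- if (n %% 2) vs[(n + 1) / 2]
                   else mean(vs[n / 2 + 0:1])
  s2 <- grid_summary(0.3, g2)
  expect_equal(s2$median[s2$measure == "ppv"], manual_median)
  expect_identical(unique(s2$n_grid), n)

  # percentile bracket always contains the median
  s3 <- grid_summary(0.2)
  expect_true(all(s3$p2.5 <= s3$median & s3$median <= s3$p97.5))
  expect_error(grid_summary(0, diagnostic_grid()), "prevalence")
  expect_error(grid_summary(1.0), "prevalence")
})

test_that("stratum sweeps order PPV and NPV with prevalence", {
  sw <- stratum_sweep(c(low = 0.2, high = 0.6))
  p_low <- sw$median[sw$stratum == "low" & sw$measure == "ppv"]
  p_high <- sw$median[sw$stratum == "high" & sw$measure == "ppv"]
  n_low <- sw$median[sw$stratum == "low" & sw$measure == "npv"]
  n_high <- sw$median[sw$stratum == "high" & sw$measure == "npv"]
  expect_lt(p_low, p_high)
  expect_gt(n_low, n_high)

  # the overall row equals grid_summary at the overall prevalence
  sw2 <- stratum_sweep(c(overall = 0.334))
  gs <- grid_summary(0.334)
  expect_equal(sw2$median, gs$median)
  expect_equal(sw2$p97.5, gs$p97.5)

  expect_error(stratum_sweep(c(0.2, 0.3)), "named")
  expect_error(stratum_sweep(c(a = 0, b = 0.3)), "strictly within")
})
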