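# Weighted stratified prevalence estimation.
#
# Point estimates are Hajek-type weighted proportions. Confidence intervals
# are Wilson intervals computed on the Kish effective sample size, so they
# respect [0,1] and deflate appropriately when weights are variable. A
# percentile bootstrap (resampling records) is available as an alternative
# CI method.

.wilson_ci <- function(p, n_eff, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  denom <- 1 + z^2 / n_eff
  centre <- (p + z^2 / (2 * n_eff)) / denom
  half <- z * sqrt(p * (1 - p) / n_eff + z^2 / (4 * n_eff^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

.resolve_weights <- function(weights, n) {
  if (inherits(weights, "weight_set")) weights <- weights$weights$weight
  stopifnot(is.numeric(weights), length(weights) == n)
  if (all(weights == 0)) stop("all weights are zero", call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  weights
}

#' Weighted proportion with confidence interval
#'
#' Hajek estimator `sum(w * x) / sum(w)` of a category proportion, with a
#' 95% Wilson interval on the Kish effective sample size (default) or a
#' percentile bootstrap over records.
#'
#' @param indicator Logical/0-1 vector marking category membership.
#' @param weights Numeric weights or a `weight_set` aligned with
#'   `indicator`.
#' @param level Confidence level.
#' @param ci_method `"wilson_neff"` (default) or `"bootstrap"`.
#' @param boot_reps Bootstrap replicates when `ci_method = "bootstrap"`.
#' @return Data frame with `proportion`, `ci_lower`, `ci_upper`, `n`
#'   (unweighted count), `n_weighted`, `n_eff`.
#' @export
weighted_proportion <- function(indicator, weights,
                                level = 0.95,
                                ci_method = c("wilson_neff", "bootstrap"),
                                boot_reps = 1000L) {
  ci_method <- match.arg(ci_method)
  if (length(indicator) == 0L) stop("empty subset", call. = FALSE)
  x <- as.numeric(indicator)
  stopifnot(all(x %in% c(0, 1)))
  w <- .resolve_weights(weights, length(x))
  p <- sum(w * x) / sum(w)
  n_eff <- kish_neff(w)
  if (ci_method == "wilson_neff") {
    ci <- .wilson_ci(p, n_eff, level)
  } else {
    reps <- vapply(seq_len(boot_reps), function(i) {
      idx <- sample.int(length(x), replace = TRUE)
      sum(w[idx] * x[idx]) / sum(w[idx])
    }, numeric(1))
    alpha <- 1 - level
    ci <- stats::quantile(reps, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    ci <- c(lower = ci[1], upper = ci[2])
  }
  data.frame(proportion = p, ci_lower = ci[["lower"]],
             ci_upper = ci[["upper"]], n = length(x),
             n_weighted = sum(w), n_eff = n_eff)
}

#' Stratified weighted prevalence table
#'
#' One weighted prevalence estimate per stratum x category cell, including
#' marginal (`"overall"`) rows. Strata are the cross-classification of the
#' requested stratifiers; categories are the levels of `category` (e.g.
#' ADNC status from [classify_adnc()] or continuum stages from
#' [stage_continuum()]). Records with a missing category are excluded;
#' empty strata are emitted with `n = 0` and `NA` proportions rather than
#' dropped.
#'
#' @param cohort Cohort data frame (analysable records).
#' @param weights Numeric weights or `weight_set` aligned with `cohort`.
#' @param category Factor/character vector aligned with `cohort`.
#' @param stratifiers Character vector of stratifier column names among
#'   `age_group`, `sex`, `education`, `cognitive_status` (an `age_group`
#'   column is derived from `age` if absent).
#' @param level,ci_method,boot_reps Passed to [weighted_proportion()].
#' @return Data frame with one row per stratum x category: stratifier
#'   columns, `category`, `proportion`, `ci_lower`, `ci_upper`, `n`,
#'   `n_weighted`, `n_eff`.
#' @export
prevalence_table <- function(cohort, weights, category,
                             stratifiers = "age_group",
                             level = 0.95,
                             ci_method = c("wilson_neff", "bootstrap"),
                             boot_reps = 1000L) {
  ci_method <- match.arg(ci_method)
  allowed <- c("age_group", "sex", "education", "cognitive_status")
  if (!all(stratifiers %in% allowed)) {
    stop("stratifiers must be among: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  cohort <- as.data.frame(cohort)
  if ("age_group" %in% stratifiers && !"age_group" %in% names(cohort)) {
    cohort$age_group <- assign_age_group(cohort$age)
  }
  w <- .resolve_weights(weights, nrow(cohort))
  category <- factor(category)
  keep <- !is.na(category)
  cohort <- cohort[keep, , drop = FALSE]
  w <- w[keep]
  category <- category[keep]

  strata_vals <- lapply(stratifiers, function(s) {
    lv <- if (is.factor(cohort[[s]])) levels(cohort[[s]])
          else sort(unique(as.character(cohort[[s]])))
    c(lv, "overall")
  })
  names(strata_vals) <- stratifiers
  grid <- expand.grid(strata_vals, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)

  out <- list()
  for (i in seq_len(nrow(grid))) {
    in_stratum <- rep(TRUE, nrow(cohort))
    for (s in stratifiers) {
      if (grid[i, s] != "overall") {
        in_stratum <- in_stratum & (as.character(cohort[[s]]) == grid[i, s])
      }
    }
    for (lev in levels(category)) {
      base <- cbind(grid[i, , drop = FALSE], category = lev,
                    row.names = NULL, stringsAsFactors = FALSE)
      if (!any(in_stratum)) {
        est <- data.frame(proportion = NA_real_, ci_lower = NA_real_,
                          ci_upper = NA_real_, n = 0L, n_weighted = 0,
                          n_eff = 0)
      } else {
        est <- weighted_proportion(category[in_stratum] == lev,
                                   w[in_stratum], level = level,
                                   ci_method = ci_method,
                                   boot_reps = boot_reps)
        est$n <- sum(in_stratum & category == lev)
        est$n_weighted <- sum(w[in_stratum & category == lev])
      }
      out[[length(out) + 1L]] <- cbind(base, est, row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Weighted chi-squared test of proportions
#'
#' Pearson chi-squared test on a groups x categories table of weighted
#' counts, with each group's counts rescaled to its Kish effective sample
#' size so that weight variability does not inflate the statistic. With
#' unit weights this is the ordinary (uncorrected) Pearson test.
#'
#' @param group Factor/character of group membership (2 or more groups).
#' @param category Factor/character of category membership.
#' @param weights Numeric weights or `weight_set`.
#' @return List of class `weighted_prop_test`: `statistic`, `df`,
#'   `p_value`, `table` (the effective-size-scaled counts), `warning`
#'   (NULL, or a note when an expected cell is below 1).
#' @export
proportion_test <- function(group, category, weights = NULL) {
  group <- factor(group)
  category <- factor(category)
  stopifnot(length(group) == length(category))
  if (nlevels(group) < 2L || nlevels(category) < 2L) {
    stop("need at least 2 groups and 2 categories", call. = FALSE)
  }
  w <- if (is.null(weights)) rep(1, length(group))
       else .resolve_weights(weights, length(group))

  tab <- matrix(0, nlevels(group), nlevels(category),
                dimnames = list(levels(group), levels(category)))
  for (g in levels(group)) {
    idx <- group == g
    wg <- w[idx]
    scale <- kish_neff(wg) / sum(wg)
    counts <- tapply(wg, category[idx], sum, default = 0)
    tab[g, ] <- counts * scale
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nlevels(group) - 1L) * (nlevels(category) - 1L)
  warn <- if (any(expected < 1)) {
    "some expected cell counts are below 1; the chi-squared approximation may be poor"
  } else NULL
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 table = tab, warning = warn),
            class = "weighted_prop_test")
}

#' @export
print.weighted_prop_test <- function(x, ...) {
  cat(sprintf("Weighted Pearson chi-squared: X^2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (!is.null(x$warning)) cat("note:", x$warning, "\n")
  invisible(x)
}

#' Adjusted comorbidity association with biomarker positivity
#'
#' Weighted logistic regression of ADNC positivity (at/above the upper
#' cutoff, versus negative or intermediate) on a comorbidity flag, adjusted
#' for age, sex, APOE e4 allele count, cognitive status, serum creatinine
#' and education. Records with a missing flag or missing creatinine are
#' excluded; categorical adjusters keep their explicit `"missing"` level.
#' Weights are rescaled to sum to the Kish effective sample size so Wald
#' intervals are not spuriously narrow. Quasi-separation triggers the same
#' ridge fallback as the stage models (no CI is then reported).
#'
#' @param cohort Analysable cohort records.
#' @param weights Numeric weights or `weight_set` aligned with `cohort`.
#' @param flag Name of the comorbidity column (tri-state yes/no/missing).
#' @param scheme A [cutoff_scheme()].
#' @param level Confidence level for the Wald interval.
#' @return Data frame with `flag`, `odds_ratio`, `ci_lower`, `ci_upper`,
#'   `p_value`, `n`, `method`.
#' @export
comorbidity_association <- function(cohort, weights, flag,
                                    scheme = cutoff_scheme(),
                                    level = 0.95) {
  if (!flag %in% names(cohort)) {
    stop("unknown comorbidity flag: ", flag, call. = FALSE)
  }
  w <- .resolve_weights(weights, nrow(cohort))
  status <- classify_adnc(cohort$ptau217, scheme)
  keep <- !is.na(status) & cohort[[flag]] %in% c("yes", "no") &
    !is.na(cohort$creatinine)
  d <- data.frame(
    y = as.integer(status[keep] == "positive"),
    flag = factor(cohort[[flag]][keep], levels = c("no", "yes")),
    age = cohort$age[keep],
    sex = factor(cohort$sex[keep]),
    apoe = factor(cohort$apoe_e4_count[keep]),
    cognition = factor(cohort$cognitive_status[keep]),
    creatinine = cohort$creatinine[keep],
    education = factor(cohort$education[keep]))
  w <- w[keep]
  w <- w * kish_neff(w) / sum(w)

  fit <- tryCatch(
    withCallingHandlers(
      stats::glm(y ~ flag + age + sex + apoe + cognition + creatinine +
                   education,
                 data = d, weights = w, family = stats::quasibinomial()),
      warning = function(wn) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  co <- if (!is.null(fit)) stats::coef(fit) else NA
  separated <- is.null(fit) || any(is.na(co)) ||
    abs(co[["flagyes"]]) > 15 || !fit$converged

  if (!separated) {
    sm <- summary(fit)$coefficients["flagyes", ]
    z <- stats::qnorm(1 - (1 - level) / 2)
    return(data.frame(flag = flag, odds_ratio = exp(sm[["Estimate"]]),
                      ci_lower = exp(sm[["Estimate"]] - z * sm[["Std. Error"]]),
                      ci_upper = exp(sm[["Estimate"]] + z * sm[["Std. Error"]]),
                      p_value = 2 * stats::pnorm(-abs(sm[["t value"]])),
                      n = nrow(d), method = "ml",
                      stringsAsFactors = FALSE))
  }
  warning("comorbidity model for '", flag, "' separated; ",
          "ridge fallback used (no confidence interval)", call. = FALSE)
  x <- stats::model.matrix(
    ~ flag + age + sex + apoe + cognition + creatinine + education,
    data = d)[, -1, drop = FALSE]
  rf <- glmnet::glmnet(x, d$y, family = "binomial", alpha = 0,
                       lambda = 1e-4, weights = w, standardize = FALSE)
  beta <- stats::coef(rf)["flagyes", 1]
  data.frame(flag = flag, odds_ratio = exp(beta), ci_lower = NA_real_,
             ci_upper = NA_real_, p_value = NA_real_, n = nrow(d),
             method = "ridge", stringsAsFactors = FALSE)
}
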