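# Treatment-eligibility estimation.
#
# Eligibility for anti-amyloid disease-modifying therapy requires an early
# symptomatic diagnosis (MCI or mild dementia by default), biomarker
# positivity on the two-cutoff scheme, and no configured exclusion.
# Missing eligibility covariates (BMI, APOE e4 count, stroke history) are
# completed by chained-equation multiple imputation before assessment; the
# weighted eligible fraction is pooled across completed datasets by the
# Rubin point rule (simple average), with the between-imputation spread
# reported.

#' Eligibility criteria
#'
#' Configurable rule set: allowed diagnoses (MCI counts as such; dementia
#' only at the allowed severities), required biomarker category, exclusion
#' on stroke history, and optional BMI bounds.
#'
#' @param allowed_diagnoses Character subset of `c("MCI", "dementia")`.
#' @param allowed_dementia_severity Severities of dementia that remain
#'   eligible (default mild only).
#' @param exclude_stroke Exclude records with `stroke_history == "yes"`.
#' @param bmi_bounds Optional `c(lower, upper)` interval; `NULL` disables.
#' @return Object of class `eligibility_criteria`.
#' @export
eligibility_criteria <- function(allowed_diagnoses = c("MCI", "dementia"),
                                 allowed_dementia_severity = "mild",
                                 exclude_stroke = TRUE,
                                 bmi_bounds = NULL) {
  stopifnot(all(allowed_diagnoses %in% c("CU", "MCI", "dementia")))
  if (!is.null(bmi_bounds)) {
    stopifnot(length(bmi_bounds) == 2L, bmi_bounds[1] < bmi_bounds[2])
  }
  structure(list(allowed_diagnoses = allowed_diagnoses,
                 allowed_dementia_severity = allowed_dementia_severity,
                 exclude_stroke = exclude_stroke,
                 bmi_bounds = bmi_bounds),
            class = "eligibility_criteria")
}

#' Imputation plan
#'
#' Chained-equation plan for the eligibility covariates. Binary and
#' three-level categorical variables are imputed by draws from (multinomial)
#' logistic models; continuous variables by predictive mean matching
#' (nearest-donor draw among the 5 closest observed predictions).
#'
#' @param variables Variables to impute.
#' @param m Number of completed datasets (at least 2).
#' @param iterations Chained-equation sweeps per dataset.
#' @param seed Integer seed; each completed dataset uses its own substream.
#' @return Object of class `imputation_plan`.
#' @export
imputation_plan <- function(variables = c("bmi", "apoe_e4_count",
                                          "stroke_history"),
                            m = 5L, iterations = 5L, seed = 1L) {
  stopifnot(m >= 2L, iterations >= 1L)
  structure(list(variables = variables, m = as.integer(m),
                 iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "imputation_plan")
}

# is the cell missing, under the package's missing conventions?
.is_missing_cell <- function(x) {
  if (is.numeric(x)) is.na(x) else x == "missing" | is.na(x)
}

.imp_predictors <- function(cohort, exclude) {
  vars <- c("age", "sex", "education", "cognitive_status", "bmi",
            "apoe_e4_count", "stroke_history")
  setdiff(vars, exclude)
}

.design_frame <- function(cohort, predictors) {
  d <- cohort[, predictors, drop = FALSE]
  for (col in names(d)) {
    if (!is.numeric(d[[col]])) d[[col]] <- factor(d[[col]])
  }
  # constant columns carry no information and break the conditional fits
  keep <- vapply(d, function(x) {
    if (is.factor(x)) nlevels(droplevels(x)) > 1
    else isTRUE(stats::var(x, na.rm = TRUE) > 0)
  }, logical(1))
  d[, keep, drop = FALSE]
}

# one conditional draw for a single variable given current completions
.impute_one <- function(target, cohort, miss) {
  predictors <- .imp_predictors(cohort, target)
  d <- .design_frame(cohort, predictors)
  # current working values may still carry numeric NAs from other chains'
  # first sweep; mean-fill them so model.matrix keeps every row
  for (col in names(d)) {
    if (is.numeric(d[[col]]) && anyNA(d[[col]])) {
      d[[col]][is.na(d[[col]])] <- mean(d[[col]], na.rm = TRUE)
    }
  }
  y <- cohort[[target]]

  if (ncol(d) == 0L) {
    # no informative predictors: draw from the observed margin
    pool <- y[!miss]
    y[miss] <- sample(pool, sum(miss), replace = TRUE)
    return(y)
  }

  if (is.numeric(y)) {
    # predictive mean matching with 5 donors
    obs <- !miss
    fit <- stats::lm(y[obs] ~ ., data = d[obs, , drop = FALSE])
    pred_obs <- stats::fitted(fit)
    pred_mis <- stats::predict(fit, newdata = d[miss, , drop = FALSE])
    donors <- vapply(pred_mis, function(p) {
      k <- order(abs(pred_obs - p))[seq_len(min(5L, sum(obs)))]
      sample(k, 1L)
    }, integer(1))
    y[miss] <- y[obs][donors]
    return(y)
  }

  lev <- setdiff(sort(unique(y[!miss])), "missing")
  obs <- !miss
  yf <- factor(y[obs], levels = lev)
  if (length(lev) == 1L) {
    y[miss] <- lev
  } else if (length(lev) == 2L) {
    fit <- suppressWarnings(
      stats::glm(yf ~ ., data = d[obs, , drop = FALSE],
                 family = stats::binomial()))
    p <- stats::predict(fit, newdata = d[miss, , drop = FALSE],
                        type = "response")
    y[miss] <- ifelse(stats::runif(sum(miss)) < p, lev[2], lev[1])
  } else {
    fit <- nnet::multinom(yf ~ ., data = d[obs, , drop = FALSE],
                          trace = FALSE)
    p <- stats::predict(fit, newdata = d[miss, , drop = FALSE],
                        type = "probs")
    if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
    u <- stats::runif(sum(miss))
    cum <- t(apply(p, 1L, cumsum))
    pick <- 1L + rowSums(cum < u)
    y[miss] <- lev[pick]
  }
  y
}

#' Chained-equation multiple imputation of eligibility covariates
#'
#' Produces `m` completed cohorts. Each sweep cycles through the plan's
#' variables in order, refitting each conditional model on the originally
#' observed cells given the current completions of everything else.
#' Observed cells are never altered; each completed dataset runs on its own
#' RNG substream derived from the plan seed. A plan variable that is
#' entirely missing is an error.
#'
#' @param cohort Cohort data frame (typically the analysable subset).
#' @param plan An [imputation_plan()].
#' @return List of `m` completed cohort data frames, with attribute
#'   `"missing_mask"` (logical matrix of originally missing cells).
#' @export
impute_missing <- function(cohort, plan = imputation_plan()) {
  stopifnot(inherits(plan, "imputation_plan"))
  absent <- setdiff(plan$variables, names(cohort))
  if (length(absent)) {
    stop("plan variables not in cohort: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  mask <- vapply(plan$variables,
                 function(v) .is_missing_cell(cohort[[v]]),
                 logical(nrow(cohort)))
  if (!is.matrix(mask)) mask <- matrix(mask, nrow = nrow(cohort))
  colnames(mask) <- plan$variables
  all_missing <- colSums(!mask) == 0L
  if (any(all_missing)) {
    stop("variable(s) entirely missing, cannot impute: ",
         paste(plan$variables[all_missing], collapse = ", "),
         call. = FALSE)
  }

  set.seed(plan$seed)
  substreams <- sample.int(.Machine$integer.max, plan$m)
  completed <- vector("list", plan$m)
  for (j in seq_len(plan$m)) {
    set.seed(substreams[j])
    work <- cohort
    # initialize missing cells by random draws from the observed margins
    for (v in plan$variables) {
      miss <- mask[, v]
      if (!any(miss)) next
      pool <- work[[v]][!miss]
      work[[v]][miss] <- sample(pool, sum(miss), replace = TRUE)
    }
    for (it in seq_len(plan$iterations)) {
      for (v in plan$variables) {
        miss <- mask[, v]
        if (!any(miss)) next
        work[[v]] <- .impute_one(v, work, miss)
      }
    }
    completed[[j]] <- work
  }
  attr(completed, "missing_mask") <- mask
  completed
}

#' Assess eligibility of fully observed records
#'
#' A record is eligible when its diagnosis is in the allowed set (dementia
#' only at an allowed severity), its pTau217 classifies as positive, no
#' exclusion flag fires, and BMI is within bounds when bounds are
#' configured. All criteria fields must be observed (run imputation first);
#' a missing field is an error.
#'
#' @param cohort Cohort data frame of analysable, completed records.
#' @param criteria An [eligibility_criteria()].
#' @param scheme A [cutoff_scheme()].
#' @return Logical vector of eligibility.
#' @export
assess_eligibility <- function(cohort, criteria = eligibility_criteria(),
                               scheme = cutoff_scheme()) {
  stopifnot(inherits(criteria, "eligibility_criteria"))
  needed <- c("cognitive_status", "ptau217")
  if (criteria$exclude_stroke) needed <- c(needed, "stroke_history")
  if (!is.null(criteria$bmi_bounds)) needed <- c(needed, "bmi")
  for (v in needed) {
    if (any(.is_missing_cell(cohort[[v]]))) {
      stop("missing values in criteria field '", v,
           "'; impute before assessing eligibility", call. = FALSE)
    }
  }
  status <- classify_adnc(cohort$ptau217, scheme)
  diag_ok <- cohort$cognitive_status %in% criteria$allowed_diagnoses &
    (cohort$cognitive_status != "dementia" |
       cohort$dementia_severity %in% criteria$allowed_dementia_severity)
  elig <- diag_ok & !is.na(status) & status == "positive"
  if (criteria$exclude_stroke) {
    elig <- elig & cohort$stroke_history != "yes"
  }
  if (!is.null(criteria$bmi_bounds)) {
    elig <- elig & cohort$bmi >= criteria$bmi_bounds[1] &
      cohort$bmi <= criteria$bmi_bounds[2]
  }
  elig
}

#' Weighted eligible proportion with multiple imputation
#'
#' For each completed dataset, the weighted eligible fraction is the
#' weighted sum of eligible records divided by the weighted sum of the
#' whole study population; the pooled estimate is the average over the `m`
#' datasets (Rubin point rule), reported with the per-imputation spread and
#' a Wilson interval on the Kish effective sample size at the pooled
#' estimate. Invariant to rescaling all weights by a constant.
#'
#' @param cohort Analysable cohort records.
#' @param weights Numeric weights or `weight_set` aligned with `cohort`.
#' @param criteria An [eligibility_criteria()].
#' @param plan An [imputation_plan()]; set `NULL` to skip imputation (the
#'   cohort must then be fully observed on the criteria fields).
#' @param scheme A [cutoff_scheme()].
#' @return Data frame with `proportion` (pooled), `ci_lower`, `ci_upper`,
#'   `min_imputation`, `max_imputation`, `between_imputation_sd`, `m`,
#'   `n`, `n_eff`.
#' @export
eligible_proportion <- function(cohort, weights,
                                criteria = eligibility_criteria(),
                                plan = imputation_plan(),
                                scheme = cutoff_scheme()) {
  w <- .resolve_weights(weights, nrow(cohort))
  datasets <- if (is.null(plan)) list(cohort)
              else impute_missing(cohort, plan)
  per_imp <- vapply(datasets, function(d) {
    elig <- assess_eligibility(d, criteria, scheme)
    sum(w * elig) / sum(w)
  }, numeric(1))
  pooled <- mean(per_imp)
  n_eff <- kish_neff(w)
  ci <- .wilson_ci(pooled, n_eff)
  data.frame(proportion = pooled, ci_lower = ci[["lower"]],
             ci_upper = ci[["upper"]],
             min_imputation = min(per_imp), max_imputation = max(per_imp),
             between_imputation_sd = stats::sd(per_imp),
             m = length(per_imp), n = nrow(cohort), n_eff = n_eff)
}
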