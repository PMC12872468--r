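# Multi-stage inverse-probability-of-selection weighting.
#
# Each stage of non-random inclusion (participation, blood donation,
# nested selection of the younger wave) gets its own logistic model fitted
# on that stage's risk set; the final weight is the inverse of the product
# of the relevant stage probabilities (two factors for the 70+ wave, three
# for the younger wave), trimmed by winsorization at median +/- 3 IQR.

#' Stage model specification
#'
#' Declares one selection stage: its name, the indicator column it models,
#' the covariates entering the logistic regression, and the risk set it is
#' fitted on (an expression over cohort columns, as a one-sided formula or
#' character).
#'
#' @param stage One of `"participation_h4"`, `"blood_donation_h4"`,
#'   `"h3_nested_selection"` or a custom label.
#' @param outcome Name of the logical outcome column.
#' @param covariates Character vector of covariate column names.
#'   Categorical covariates keep `"missing"` as its own level.
#' @param risk_set Character string with an R expression over cohort
#'   columns selecting the records the stage applies to (default: all).
#' @return An object of class `stage_model_spec`.
#' @export
stage_model_spec <- function(stage, outcome, covariates,
                             risk_set = "TRUE") {
  structure(list(stage = stage, outcome = outcome,
                 covariates = covariates, risk_set = risk_set),
            class = "stage_model_spec")
}

#' Default stage specifications
#'
#' The three stages of the weighting strategy: (1) participation, modeled
#' on age, sex and education over the full invitation frame; (2) blood
#' donation among participants, modeled on age, sex, education, APOE e4
#' status, cognitive diagnosis and the self-reported comorbidity flags;
#' (3) nested selection of the younger wave among its blood donors, same
#' covariate set.
#'
#' @return Named list of [stage_model_spec()] objects.
#' @export
default_stage_specs <- function() {
  rich <- c("age", "sex", "education", "apoe_e4_count", "cognitive_status",
            comorbidity_flags())
  list(
    participation_h4 = stage_model_spec(
      "participation_h4", outcome = "participated",
      covariates = c("age", "sex", "education")),
    blood_donation_h4 = stage_model_spec(
      "blood_donation_h4", outcome = "gave_blood",
      covariates = rich, risk_set = "participated"),
    h3_nested_selection = stage_model_spec(
      "h3_nested_selection", outcome = "selected_into_substudy",
      covariates = rich,
      risk_set = "cohort_wave == \"H3\" & gave_blood"))
}

.stage_design <- function(cohort, spec) {
  d <- cohort[, spec$covariates, drop = FALSE]
  for (col in names(d)) {
    if (!is.numeric(d[[col]])) d[[col]] <- factor(d[[col]])
  }
  # drop factors with a single observed level (no information, breaks glm)
  keep <- vapply(d, function(x) !is.factor(x) || nlevels(droplevels(x)) > 1,
                 logical(1))
  d <- d[, keep, drop = FALSE]
  d
}

#' Fit a stage participation probability model
#'
#' Maximum-likelihood logistic regression of the stage's inclusion
#' indicator on its covariates, over the stage's risk set. Missing
#' categorical levels enter as their own `"missing"` level. A constant
#' outcome yields degenerate probabilities (all ~0 or ~1) with a warning.
#' If the ML fit fails to converge or separates, the model is refitted with
#' a small ridge penalty (glmnet, `lambda = 1e-4`) and a warning is issued.
#'
#' @param cohort Cohort data frame.
#' @param spec A [stage_model_spec()].
#' @return List of class `stage_fit`: `stage`, `probabilities` (named by
#'   record id, risk set only), `risk_set` (logical over the cohort),
#'   `coefficients`, `converged`, `method` (`"ml"`, `"ridge"` or
#'   `"degenerate"`).
#' @export
fit_stage_probability <- function(cohort, spec) {
  stopifnot(inherits(spec, "stage_model_spec"))
  missing_cov <- setdiff(c(spec$outcome, spec$covariates), names(cohort))
  if (length(missing_cov)) {
    stop("stage '", spec$stage, "': columns not in cohort: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  in_risk <- eval(parse(text = spec$risk_set), cohort, baseenv())
  if (length(in_risk) == 1L) in_risk <- rep(in_risk, nrow(cohort))
  sub <- cohort[in_risk, , drop = FALSE]
  y <- sub[[spec$outcome]]
  if (any(is.na(y))) {
    stop("stage '", spec$stage, "': outcome undefined within risk set",
         call. = FALSE)
  }

  if (length(unique(y)) < 2L) {
    warning("stage '", spec$stage, "' is degenerate: outcome is constant; ",
            "probabilities set to the observed rate", call. = FALSE)
    eps <- 1e-8
    p <- rep(max(eps, min(1 - eps, mean(y))), nrow(sub))
    return(structure(list(stage = spec$stage,
                          probabilities = stats::setNames(p, sub$id),
                          risk_set = in_risk, coefficients = NULL,
                          converged = TRUE, method = "degenerate"),
                     class = "stage_fit"))
  }

  d <- .stage_design(sub, spec)
  df <- cbind(.y = as.integer(y), d)
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  separated <- !fit$converged ||
    any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE) ||
    any(is.na(stats::coef(fit)))

  if (!separated) {
    p <- stats::fitted(fit)
    return(structure(list(stage = spec$stage,
                          probabilities = stats::setNames(unname(p), sub$id),
                          risk_set = in_risk,
                          coefficients = stats::coef(fit),
                          converged = TRUE, method = "ml"),
                     class = "stage_fit"))
  }

  warning("stage '", spec$stage, "': ML fit separated or failed to ",
          "converge; refitting with a small ridge penalty", call. = FALSE)
  x <- stats::model.matrix(~ ., data = d)[, -1, drop = FALSE]
  rf <- glmnet::glmnet(x, as.integer(y), family = "binomial", alpha = 0,
                       lambda = 1e-4, standardize = FALSE)
  p <- as.numeric(stats::predict(rf, newx = x, type = "response"))
  eps <- 1e-8
  p <- pmin(1 - eps, pmax(eps, p))
  structure(list(stage = spec$stage,
                 probabilities = stats::setNames(p, sub$id),
                 risk_set = in_risk,
                 coefficients = stats::setNames(
                   as.numeric(stats::coef(rf)), rownames(stats::coef(rf))),
                 converged = TRUE, method = "ridge"),
            class = "stage_fit")
}

#' Compose inverse-probability weights
#'
#' Builds the raw per-record weight as the inverse product of the relevant
#' stage probabilities: two factors (participation, blood donation) for 70+
#' records, three (participation, blood donation, nested selection) for
#' younger-wave records. Weights are produced for the analysable records
#' (observed pTau217 samples, see [analysis_rows()]).
#'
#' @param cohort Cohort data frame.
#' @param stage_fits Named list of `stage_fit` objects from
#'   [fit_stage_probability()], containing `participation_h4`,
#'   `blood_donation_h4` and (if younger-wave records are present)
#'   `h3_nested_selection`.
#' @return An object of class `weight_set`: data frame `weights` (`id`,
#'   per-stage probabilities, `raw_weight`, `weight`), plus `trimmed`
#'   flag and trim `bounds` (filled by [trim_weights()]).
#' @export
compose_weights <- function(cohort, stage_fits) {
  rows <- analysis_rows(cohort)
  ids <- cohort$id[rows]
  wave <- cohort$cohort_wave[rows]

  get_p <- function(stage, need) {
    fit <- stage_fits[[stage]]
    if (is.null(fit)) {
      if (any(need)) stop("missing stage fit: ", stage, call. = FALSE)
      return(rep(NA_real_, length(ids)))
    }
    p <- fit$probabilities[ids]
    bad <- need & (is.na(p) | p <= 0 | p >= 1 + 1e-12)
    if (any(bad)) {
      stop("stage '", stage, "': missing or out-of-range probability for ",
           "record(s) ", paste(utils::head(ids[bad], 5L), collapse = ", "),
           call. = FALSE)
    }
    unname(p)
  }

  p_part <- get_p("participation_h4", rep(TRUE, length(ids)))
  p_blood <- get_p("blood_donation_h4", rep(TRUE, length(ids)))
  p_sel <- get_p("h3_nested_selection", wave == "H3")

  prod_p <- p_part * p_blood
  prod_p[wave == "H3"] <- prod_p[wave == "H3"] * p_sel[wave == "H3"]
  raw <- 1 / prod_p

  structure(list(
    weights = data.frame(id = ids, p_participation = p_part,
                         p_blood_donation = p_blood,
                         p_nested_selection = p_sel,
                         raw_weight = raw, weight = raw,
                         stringsAsFactors = FALSE),
    trimmed = FALSE, bounds = c(lower = NA_real_, upper = NA_real_)),
    class = "weight_set")
}

#' Construct a weight set from bare weights
#'
#' Convenience constructor used when weights come from outside the staged
#' pipeline (unit weights, externally supplied weights).
#'
#' @param weight Positive numeric vector.
#' @param id Optional record identifiers.
#' @return A `weight_set`.
#' @export
weight_set <- function(weight, id = NULL) {
  stopifnot(is.numeric(weight), all(weight > 0))
  if (is.null(id)) id <- as.character(seq_along(weight))
  structure(list(
    weights = data.frame(id = id, p_participation = NA_real_,
                         p_blood_donation = NA_real_,
                         p_nested_selection = NA_real_,
                         raw_weight = weight, weight = weight,
                         stringsAsFactors = FALSE),
    trimmed = FALSE, bounds = c(lower = NA_real_, upper = NA_real_)),
    class = "weight_set")
}

#' Trim weights by winsorization at median +/- 3 IQR
#'
#' Clips (does not exclude) the raw weights to
#' `[max(eps, median - 3 IQR), median + 3 IQR]`, with quartiles by linear
#' interpolation between order statistics (`stats::quantile` type 7) and
#' `eps` the smallest positive double, so that a negative lower bound can
#' never produce non-positive weights. With a degenerate IQR of zero every
#' weight collapses to the median. The applied bounds are recorded in the
#' returned set.
#'
#' @param ws A `weight_set` with raw weights.
#' @return The `weight_set` with `weight` winsorized, `trimmed = TRUE` and
#'   `bounds` recorded.
#' @export
trim_weights <- function(ws) {
  stopifnot(inherits(ws, "weight_set"))
  raw <- ws$weights$raw_weight
  if (length(raw) < 2L) {
    stop("weight trimming needs at least 2 weights", call. = FALSE)
  }
  q <- stats::quantile(raw, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lower <- max(.Machine$double.xmin, q[2] - 3 * iqr)
  upper <- q[2] + 3 * iqr
  ws$weights$weight <- pmin(upper, pmax(lower, raw))
  ws$trimmed <- TRUE
  ws$bounds <- c(lower = lower, upper = upper)
  ws
}

#' @export
print.weight_set <- function(x, ...) {
  w <- x$weights$weight
  cat(sprintf(
    "weight_set: %d records, %s; weight range [%.3g, %.3g], Kish n_eff %.1f\n",
    length(w), if (x$trimmed) sprintf("trimmed to [%.3g, %.3g]",
                                      x$bounds["lower"], x$bounds["upper"])
               else "untrimmed",
    min(w), max(w), kish_neff(w)))
  invisible(x)
}

#' Kish effective sample size
#'
#' `(sum w)^2 / sum(w^2)`: the unweighted sample size carrying the same
#' information as the weighted sample.
#'
#' @param w Positive numeric weights.
#' @return Scalar effective sample size.
#' @export
kish_neff <- function(w) sum(w)^2 / sum(w^2)
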