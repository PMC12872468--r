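#' Two-cutoff classification scheme
#'
#' The rule-out / rule-in pair of plasma pTau217 thresholds. The lower
#' cutoff (default 0.40 pg/ml) is chosen for high sensitivity: values
#' strictly below it are called ADNC negative. The upper cutoff (default
#' 0.63 pg/ml) is chosen for high specificity: values at or above it are
#' called ADNC positive. Everything in between is the intermediate zone.
#'
#' @param lower Lower cutoff in pg/ml.
#' @param upper Upper cutoff in pg/ml.
#' @return An object of class `cutoff_scheme`.
#' @export
cutoff_scheme <- function(lower = 0.40, upper = 0.63) {
  stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == 1L,
            length(upper) == 1L)
  if (!(lower > 0 && lower < upper)) {
    stop("cutoffs must satisfy 0 < lower < upper", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper), class = "cutoff_scheme")
}

#' @export
print.cutoff_scheme <- function(x, ...) {
  cat(sprintf("Two-cutoff scheme: negative < %.2f <= intermediate < %.2f <= positive (pg/ml)\n",
              x$lower, x$upper))
  invisible(x)
}

#' Classify ADNC status from plasma pTau217
#'
#' Three-level classification: concentrations strictly below the lower
#' cutoff are `negative`, at or above the upper cutoff `positive`, and
#' otherwise `intermediate` (so the boundary value 0.40 itself is
#' intermediate, and 0.63 is positive). Missing concentrations propagate
#' as `NA`.
#'
#' @param ptau217 Numeric vector of concentrations in pg/ml (`NA` allowed).
#' @param scheme A [cutoff_scheme()].
#' @return Factor with levels `negative`, `intermediate`, `positive`.
#' @export
classify_adnc <- function(ptau217, scheme = cutoff_scheme()) {
  stopifnot(inherits(scheme, "cutoff_scheme"))
  if (any(!is.na(ptau217) & ptau217 <= 0)) {
    stop("pTau217 concentrations must be positive", call. = FALSE)
  }
  out <- ifelse(is.na(ptau217), NA_character_,
                ifelse(ptau217 < scheme$lower, "negative",
                       ifelse(ptau217 >= scheme$upper, "positive",
                              "intermediate")))
  factor(out, levels = adnc_levels())
}

#' ADNC category levels
#' @return Character vector `c("negative", "intermediate", "positive")`.
#' @export
adnc_levels <- function() c("negative", "intermediate", "positive")

#' Continuum stage levels
#' @return Character vector of the five AD-continuum stages.
#' @export
continuum_levels <- function() {
  c("preclinical_AD", "prodromal_AD", "AD_dementia", "not_on_continuum",
    "indeterminate")
}

#' Stage the AD continuum
#'
#' Crosses ADNC status with the cognitive diagnosis: biomarker-positive and
#' cognitively unimpaired is preclinical AD, positive with MCI is prodromal
#' AD, positive with dementia is AD dementia. Biomarker-negative individuals
#' are not on the continuum regardless of diagnosis (their impairment, if
#' any, is attributed to non-AD causes). An intermediate biomarker or an
#' undetermined diagnosis yields `indeterminate`. Total function; missing
#' status propagates as `NA`.
#'
#' @param status Factor/character of ADNC categories (see [classify_adnc()]).
#' @param diagnosis Character vector: `CU`, `MCI`, `dementia` or
#'   `undetermined`.
#' @return Factor with levels [continuum_levels()].
#' @export
stage_continuum <- function(status, diagnosis) {
  status <- as.character(status)
  diagnosis <- as.character(diagnosis)
  stopifnot(length(status) == length(diagnosis))
  bad <- !is.na(diagnosis) & !(diagnosis %in% .levels$cognitive_status)
  if (any(bad)) {
    stop("unknown cognitive status: ",
         paste(unique(diagnosis[bad]), collapse = ", "), call. = FALSE)
  }
  out <- rep(NA_character_, length(status))
  out[!is.na(status) &
        (status == "intermediate" | diagnosis == "undetermined")] <-
    "indeterminate"
  # a negative biomarker rules the continuum out even without an assessment
  out[!is.na(status) & status == "negative"] <- "not_on_continuum"
  pos <- !is.na(status) & status == "positive" & diagnosis != "undetermined"
  out[pos & diagnosis == "CU"] <- "preclinical_AD"
  out[pos & diagnosis == "MCI"] <- "prodromal_AD"
  out[pos & diagnosis == "dementia"] <- "AD_dementia"
  factor(out, levels = continuum_levels())
}
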