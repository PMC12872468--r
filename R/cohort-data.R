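# Canonical column order and types for the participant-level cohort table.
# Categorical missingness is an explicit "missing" level; numeric
# missingness is NA (empty cell on disk). Creatinine is mg/dl only
# (divide umol/l values by 88.42 before import).

#' Comorbidity flag vocabulary
#'
#' Names of the self-reported comorbidity indicator columns in the cohort
#' schema. Each is a tri-state character column: `"yes"`, `"no"` or
#' `"missing"`.
#'
#' @return Character vector of column names.
#' @export
comorbidity_flags <- function() {
  c("cardiovascular", "cerebrovascular", "copd", "diabetes", "cancer",
    "migraine", "psoriasis", "kidney_disease", "rheumatoid_arthritis",
    "gout")
}

#' Cohort table schema
#'
#' Column names, in canonical order, of the participant-level cohort table
#' consumed by all estimation stages.
#'
#' @return Character vector of column names.
#' @export
cohort_schema <- function() {
  c("id", "cohort_wave", "age", "sex", "education", "apoe_e4_count",
    "cognitive_status", "dementia_severity", "ptau217", "creatinine",
    "bmi", "stroke_history", comorbidity_flags(),
    "participated", "gave_blood", "selected_into_substudy")
}

.levels <- list(
  cohort_wave       = c("H3", "H4"),
  sex               = c("female", "male"),
  education         = c("primary", "secondary", "tertiary", "missing"),
  apoe_e4_count     = c("0", "1", "2", "missing"),
  cognitive_status  = c("CU", "MCI", "dementia", "undetermined"),
  dementia_severity = c("mild", "moderate", "severe", "not_applicable"),
  tri_state         = c("yes", "no", "missing")
)

#' Validate a cohort table
#'
#' Checks the schema and the record-level invariants: ages at least 58 with
#' the wave split at 70, pTau217 present only for blood donors, dementia
#' severity consistent with the dementia diagnosis, and legal category
#' levels everywhere.
#'
#' @param cohort A data frame following [cohort_schema()].
#' @return The validated cohort, invisibly.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_schema(), names(cohort))
  extra_cols <- setdiff(names(cohort), cohort_schema())
  if (length(missing_cols) || length(extra_cols)) {
    stop("cohort schema mismatch; missing columns: [",
         paste(missing_cols, collapse = ", "), "]; unexpected columns: [",
         paste(extra_cols, collapse = ", "), "]", call. = FALSE)
  }

  fail <- function(rows, what) {
    if (any(rows)) {
      stop("invariant violated (", what, ") for record id(s): ",
           paste(utils::head(cohort$id[rows], 5L), collapse = ", "),
           if (sum(rows) > 5L) sprintf(" (and %d more)", sum(rows) - 5L),
           call. = FALSE)
    }
  }

  level_cols <- c(cohort_wave = "cohort_wave", sex = "sex",
                  education = "education", apoe_e4_count = "apoe_e4_count",
                  cognitive_status = "cognitive_status",
                  dementia_severity = "dementia_severity")
  for (col in level_cols) {
    fail(!(cohort[[col]] %in% .levels[[col]]), paste0("illegal ", col))
  }
  for (col in c("stroke_history", comorbidity_flags())) {
    fail(!(cohort[[col]] %in% .levels$tri_state),
         paste0("illegal tri-state in ", col))
  }
  for (col in c("participated", "gave_blood", "selected_into_substudy")) {
    fail(!is.logical(cohort[[col]]) | is.na(cohort[[col]]),
         paste0("non-boolean ", col))
  }

  fail(is.na(cohort$age) | cohort$age < 58, "age >= 58")
  fail(cohort$cohort_wave == "H3" & cohort$age >= 70, "H3 age < 70")
  fail(cohort$cohort_wave == "H4" & cohort$age < 70, "H4 age >= 70")
  fail(!is.na(cohort$ptau217) & !cohort$gave_blood,
       "ptau217 present requires gave_blood")
  fail(!is.na(cohort$ptau217) & cohort$ptau217 <= 0, "ptau217 > 0")
  fail(!is.na(cohort$creatinine) & cohort$creatinine <= 0, "creatinine > 0")
  fail((cohort$cognitive_status == "dementia") !=
         (cohort$dementia_severity != "not_applicable"),
       "dementia_severity consistent with dementia diagnosis")
  fail(cohort$cohort_wave == "H4" &
         cohort$cognitive_status == "undetermined" & cohort$participated,
       "H4 participants have an assessed cognitive status")

  invisible(cohort)
}

#' Read a cohort table
#'
#' Reads and validates a participant-level cohort table. CSV is the primary
#' interchange format (RFC 4180, UTF-8, header row); `"columnar"` reads an
#' Arrow/Feather file and requires the arrow package.
#'
#' @param path File path.
#' @param format `"csv"` (default) or `"columnar"`.
#' @return A validated cohort data frame.
#' @export
read_cohort <- function(path, format = c("csv", "columnar")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "csv") {
    cohort <- utils::read.csv(path, colClasses = .csv_classes(),
                              na.strings = "", check.names = FALSE,
                              fileEncoding = "UTF-8")
  } else {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the 'arrow' package is required for format = \"columnar\"",
           call. = FALSE)
    }
    cohort <- as.data.frame(arrow::read_feather(path))
  }
  validate_cohort(cohort)
  cohort
}

#' Write a cohort table
#'
#' Inverse of [read_cohort()]; round-trips every field including the
#' explicit missing states.
#'
#' @param cohort Validated cohort data frame.
#' @param path Output file path.
#' @param format `"csv"` (default) or `"columnar"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("csv", "columnar")) {
  format <- match.arg(format)
  validate_cohort(cohort)
  if (format == "csv") {
    utils::write.csv(cohort, path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  } else {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the 'arrow' package is required for format = \"columnar\"",
           call. = FALSE)
    }
    arrow::write_feather(cohort, path)
  }
  invisible(path)
}

.csv_classes <- function() {
  cls <- stats::setNames(rep("character", length(cohort_schema())),
                         cohort_schema())
  cls[c("age", "ptau217", "creatinine", "bmi")] <- "numeric"
  cls[c("participated", "gave_blood", "selected_into_substudy")] <- "logical"
  cls
}

#' Recode self-reported education into three levels
#'
#' Collapses the raw study coding into primary (up to 10 years of compulsory
#' primary and lower secondary schooling), secondary (1-2 or 3 years of
#' academic or vocational school, or 3-4 years of vocational
#' training/apprenticeship) and tertiary (any college or university
#' education). Missing propagates.
#'
#' @param raw Character vector of raw codes; see Details.
#' @return Character vector with levels `primary`, `secondary`, `tertiary`,
#'   `missing`.
#' @details Accepted raw codes: `"primary_lower_secondary_le10y"`,
#'   `"academic_vocational_1_2y"`, `"academic_vocational_3y"`,
#'   `"vocational_apprenticeship_3_4y"`, `"college_university_lt4y"`,
#'   `"college_university_ge4y"`, `"missing"` (or `NA`).
#' @export
recode_education <- function(raw) {
  map <- c(primary_lower_secondary_le10y  = "primary",
           academic_vocational_1_2y       = "secondary",
           academic_vocational_3y         = "secondary",
           vocational_apprenticeship_3_4y = "secondary",
           college_university_lt4y        = "tertiary",
           college_university_ge4y        = "tertiary",
           missing                        = "missing")
  raw <- as.character(raw)
  raw[is.na(raw)] <- "missing"
  unknown <- setdiff(unique(raw), names(map))
  if (length(unknown)) {
    stop("unknown education code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unname(map[raw])
}

#' Canonical age-group boundaries
#'
#' Half-open strata `[58,70)`, `[70,75)`, `[75,80)`, `[80,85)`, `[85,90)`,
#' `[90,Inf)` partitioning ages 58 and above.
#'
#' @return Numeric vector of lower boundaries plus `Inf` as the final upper
#'   bound, suitable for `cut(..., right = FALSE)`.
#' @export
age_group_breaks <- function() c(58, 70, 75, 80, 85, 90, Inf)

#' Assign an age group
#'
#' Maps age in years to its half-open stratum, so an exact 70th birthday
#' falls in `[70,75)` and 90.0 in `[90,Inf)`.
#'
#' @param age Numeric vector, all values at least 58.
#' @return Factor with levels `"[58,70)"`, `"[70,75)"`, `"[75,80)"`,
#'   `"[80,85)"`, `"[85,90)"`, `"[90,Inf)"`.
#' @export
assign_age_group <- function(age) {
  if (any(is.na(age)) || any(age < 58)) {
    stop("age must be >= 58 and non-missing", call. = FALSE)
  }
  br <- age_group_breaks()
  labs <- paste0("[", br[-length(br)], ",", c(br[-c(1, length(br))], "Inf"),
                 ")")
  cut(age, breaks = br, labels = labs, right = FALSE)
}
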