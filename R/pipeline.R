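# End-to-end orchestration: simulate or ingest a cohort, classify, weight,
# estimate prevalence, sweep predictive values, fit the kidney model, and
# estimate treatment eligibility -- all from one serializable config, with
# every intermediate written as a plain table so stages compose via files.

#' Pipeline configuration
#'
#' Fully serializable run configuration. A run is reproducible from the
#' config alone: the seed drives the simulation (when no input path is
#' given) and the imputation substreams.
#'
#' @param input Path to an existing cohort table, or `NULL` to simulate.
#' @param input_format `"csv"` or `"columnar"` when `input` is given.
#' @param simulation A [sim_config()] used when `input` is `NULL`.
#' @param scheme A [cutoff_scheme()].
#' @param grid A [diagnostic_grid()].
#' @param lambda Optimism shrinkage level for the predictive-value sweep.
#' @param segmented_resolution Breakpoint grid step for the kidney model.
#' @param criteria An [eligibility_criteria()].
#' @param plan An [imputation_plan()].
#' @param out_dir Output directory (created if absent).
#' @param seed Integer master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, input_format = "csv",
                            simulation = sim_config(),
                            scheme = cutoff_scheme(),
                            grid = diagnostic_grid(),
                            lambda = 0.9,
                            segmented_resolution = 0.5,
                            criteria = eligibility_criteria(),
                            plan = imputation_plan(),
                            out_dir = "adncprev-run",
                            seed = 1L) {
  structure(list(input = input, input_format = input_format,
                 simulation = simulation, scheme = scheme, grid = grid,
                 lambda = lambda,
                 segmented_resolution = segmented_resolution,
                 criteria = criteria, plan = plan, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Reads a config document and builds a [pipeline_config()]; unspecified
#' blocks fall back to package defaults. Scalar overrides are supported for
#' cutoffs, the grid, lambda, the segmented resolution, sizes and seeds of
#' the simulation, imputation `m`, and the output directory.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  take <- function(block, builder) {
    if (is.null(raw[[block]])) builder() else do.call(builder, raw[[block]])
  }
  pipeline_config(
    input = raw$input,
    input_format = if (is.null(raw$input_format)) "csv" else raw$input_format,
    simulation = take("simulation", sim_config),
    scheme = take("scheme", cutoff_scheme),
    grid = take("grid", diagnostic_grid),
    lambda = if (is.null(raw$lambda)) 0.9 else raw$lambda,
    segmented_resolution = if (is.null(raw$segmented_resolution)) 0.5
                           else raw$segmented_resolution,
    criteria = take("criteria", eligibility_criteria),
    plan = take("plan", imputation_plan),
    out_dir = if (is.null(raw$out_dir)) "adncprev-run" else raw$out_dir,
    seed = if (is.null(raw$seed)) 1L else raw$seed)
}

.log_stage <- function(stage, n_in, n_out, level = "info") {
  message(sprintf("[%s] %s: %d records in, %d out", level, stage, n_in,
                  n_out))
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, two-cutoff classification, multi-stage
#' inverse-probability weighting with trimming, stratified weighted
#' prevalence of ADNC categories and AD-continuum stages, the
#' predictive-value grid sweep at the estimated stratum prevalences (with
#' and without shrinkage), the segmented eGFR model, and the eligibility
#' estimate. Every table is written under `config$out_dir` along with the
#' resolved seed and a run manifest. Deterministic given the config.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with all in-memory results (`cohort`,
#'   `weights`, `prevalence_age`, `prevalence_diagnosis`,
#'   `continuum_age_sex`, `predictive_values`, `kidney`, `eligibility`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_fn <- if (quiet) function(...) invisible() else .log_stage
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- ingest / simulate ---------------------------------------------------
  if (!is.null(config$input)) {
    cohort <- read_cohort(config$input, config$input_format)
    input_desc <- config$input
  } else {
    sim <- config$simulation
    sim$seed <- config$seed
    cohort <- generate_cohort(sim)$cohort
    input_desc <- sprintf("simulated (seed %d)", config$seed)
  }
  write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
  log_fn("ingest", nrow(cohort), nrow(cohort))

  # --- weights -------------------------------------------------------------
  specs <- default_stage_specs()
  has_h3 <- any(cohort$cohort_wave == "H3" &
                  cohort$selected_into_substudy)
  if (!has_h3) specs$h3_nested_selection <- NULL
  fits <- lapply(specs, function(s) fit_stage_probability(cohort, s))
  ws <- trim_weights(compose_weights(cohort, fits))
  obs <- cohort[analysis_rows(cohort), , drop = FALSE]
  stopifnot(identical(obs$id, ws$weights$id))
  utils::write.csv(ws$weights, file.path(config$out_dir, "weights.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(fits, function(f) list(stage = f$stage, method = f$method,
                                  coefficients = as.list(f$coefficients))),
    file.path(config$out_dir, "stage_models.json"), auto_unbox = TRUE,
    digits = NA)
  log_fn("weights", nrow(cohort), nrow(obs))

  # --- classification + prevalence ----------------------------------------
  w <- ws$weights$weight
  status <- classify_adnc(obs$ptau217, config$scheme)
  stage <- stage_continuum(status, obs$cognitive_status)
  prev_age <- prevalence_table(obs, w, status, "age_group")
  prev_dx <- prevalence_table(obs[obs$cohort_wave == "H4", ],
                              w[obs$cohort_wave == "H4"],
                              status[obs$cohort_wave == "H4"],
                              "cognitive_status")
  cont_age_sex <- prevalence_table(obs, w, stage, c("age_group", "sex"))
  utils::write.csv(prev_age,
                   file.path(config$out_dir, "prevalence_by_age.csv"),
                   row.names = FALSE)
  utils::write.csv(prev_dx,
                   file.path(config$out_dir, "prevalence_by_diagnosis.csv"),
                   row.names = FALSE)
  utils::write.csv(cont_age_sex,
                   file.path(config$out_dir, "continuum_by_age_sex.csv"),
                   row.names = FALSE)
  log_fn("prevalence", nrow(obs), nrow(prev_age))

  # --- predictive values ---------------------------------------------------
  pos_rows <- prev_age$category == "positive" & !is.na(prev_age$proportion) &
    prev_age$proportion > 0 & prev_age$proportion < 1
  prevs <- stats::setNames(prev_age$proportion[pos_rows],
                           ifelse(prev_age$age_group[pos_rows] == "overall",
                                  "overall", prev_age$age_group[pos_rows]))
  pv <- rbind(cbind(shrinkage = "none",
                    stratum_sweep(prevs, config$grid, lambda = 1)),
              cbind(shrinkage = sprintf("lambda=%.2f", config$lambda),
                    stratum_sweep(prevs, config$grid,
                                  lambda = config$lambda)))
  utils::write.csv(pv, file.path(config$out_dir, "predictive_values.csv"),
                   row.names = FALSE)
  log_fn("predictive_values", length(prevs), nrow(pv))

  # --- kidney --------------------------------------------------------------
  kid_rows <- !is.na(obs$creatinine) & !is.na(obs$ptau217)
  egfr <- egfr_ckd_epi_2021(obs$creatinine[kid_rows], obs$age[kid_rows],
                            obs$sex[kid_rows])
  seg <- fit_segmented(egfr, log(obs$ptau217[kid_rows]), w[kid_rows],
                       resolution = config$segmented_resolution)
  pred <- predict_segmented(seg, seq(floor(min(egfr)), ceiling(max(egfr)),
                                     by = 1))
  jsonlite::write_json(unclass(seg),
                       file.path(config$out_dir, "segmented_fit.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(pred,
                   file.path(config$out_dir, "segmented_predictions.csv"),
                   row.names = FALSE)
  log_fn("kidney", sum(kid_rows), nrow(pred))

  # --- eligibility (70+ wave) ---------------------------------------------
  h4 <- obs$cohort_wave == "H4"
  plan <- config$plan
  plan$seed <- config$seed
  elig <- eligible_proportion(obs[h4, , drop = FALSE], w[h4],
                              config$criteria, plan, config$scheme)
  jsonlite::write_json(as.list(elig),
                       file.path(config$out_dir, "eligibility.json"),
                       auto_unbox = TRUE, digits = NA)
  log_fn("eligibility", sum(h4), 1L)

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("adncprev")),
    seed = config$seed, input = input_desc,
    n_records = nrow(cohort), n_analysable = nrow(obs),
    cutoffs = unclass(config$scheme), lambda = config$lambda,
    weight_bounds = as.list(ws$bounds),
    artifacts = c("cohort.csv", "weights.csv", "stage_models.json",
                  "prevalence_by_age.csv", "prevalence_by_diagnosis.csv",
                  "continuum_by_age_sex.csv", "predictive_values.csv",
                  "segmented_fit.json", "segmented_predictions.csv",
                  "eligibility.json"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, weights = ws, prevalence_age = prev_age,
                 prevalence_diagnosis = prev_dx,
                 continuum_age_sex = cont_age_sex, predictive_values = pv,
                 kidney = seg, eligibility = elig, manifest = manifest))
}
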