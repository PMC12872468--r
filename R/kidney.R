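# Kidney function and the pTau217-eGFR relationship.
#
# eGFR from the CKD-EPI 2021 race-free creatinine equation; the biomarker
# is log-transformed (natural log) and regressed on eGFR with a continuous
# two-segment (broken-stick) weighted least-squares model whose breakpoint
# is found by profile grid search over the interior of the observed eGFR
# range.

#' eGFR by the CKD-EPI 2021 creatinine equation
#'
#' Race-free 2021 equation:
#' `eGFR = 142 * min(Scr/k, 1)^a * max(Scr/k, 1)^-1.200 * 0.9938^age *
#' 1.012[female]`, with `k = 0.7` (female) / `0.9` (male) and
#' `a = -0.241` (female) / `-0.302` (male). Constants are from the 2021
#' CKD-EPI publication (NEJM 385:1737-1749); serum creatinine must be in
#' mg/dl (divide umol/l values by 88.42).
#'
#' @param creatinine Serum creatinine in mg/dl (positive).
#' @param age Age in years (at least 18).
#' @param sex `"female"` or `"male"` (vectorized).
#' @return eGFR in ml/min per 1.73 m^2.
#' @export
egfr_ckd_epi_2021 <- function(creatinine, age, sex) {
  ok <- !is.na(creatinine)
  if (any(creatinine[ok] <= 0)) {
    stop("creatinine must be positive (mg/dl)", call. = FALSE)
  }
  if (any(age < 18, na.rm = TRUE)) {
    stop("the CKD-EPI 2021 equation applies to adults (age >= 18)",
         call. = FALSE)
  }
  if (!all(sex %in% c("female", "male"))) {
    stop("sex must be \"female\" or \"male\"", call. = FALSE)
  }
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.241, -0.302)
  r <- creatinine / kappa
  142 * pmin(r, 1)^alpha * pmax(r, 1)^(-1.200) * 0.9938^age *
    ifelse(female, 1.012, 1)
}

#' Fit a continuous two-segment weighted regression
#'
#' Weighted least squares of log pTau217 on eGFR allowing different slopes
#' on either side of a breakpoint `psi`, with the mean function constrained
#' continuous at `psi`. The breakpoint is chosen by profile grid search:
#' for each candidate on a fixed-resolution grid spanning the interior
#' (5th-95th percentile) of the observed eGFR values, the model
#' `log_ptau ~ egfr + pmax(egfr - psi, 0)` is fitted by weighted least
#' squares and the candidate minimizing the weighted SSE wins (ties go to
#' the smallest `psi`, flagged). The segmented SSE can never exceed the
#' single-line SSE beyond grid resolution because the hinge term nests the
#' straight line.
#'
#' @param egfr Numeric predictor (ml/min per 1.73 m^2).
#' @param log_ptau Natural-log pTau217 response.
#' @param weights Positive weights (scale-invariant) or a `weight_set`.
#' @param resolution Candidate-grid step in eGFR units.
#' @param interior Percentile pair restricting the candidate range.
#' @return Object of class `segmented_fit`: `psi`, `intercept` (at
#'   `egfr = 0` on the left segment), `slope_left`, `slope_right`, `sse`
#'   (weighted), `sse_line` (single-line fit), `resolution`, `tie` flag,
#'   `n`.
#' @export
fit_segmented <- function(egfr, log_ptau, weights = NULL,
                          resolution = 0.1, interior = c(0.05, 0.95)) {
  keep <- !is.na(egfr) & !is.na(log_ptau)
  egfr <- egfr[keep]
  log_ptau <- log_ptau[keep]
  w <- if (is.null(weights)) rep(1, length(egfr))
       else .resolve_weights(weights, length(keep))[keep]
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  if (length(egfr) < 20L) {
    stop("segmented fit needs at least 20 observations", call. = FALSE)
  }

  rng <- stats::quantile(egfr, interior, names = FALSE, type = 7)
  candidates <- seq(rng[1], rng[2], by = resolution)
  if (length(candidates) == 0L) {
    stop("no interior breakpoint candidates", call. = FALSE)
  }

  wsse <- function(fit) sum(w * stats::resid(fit)^2)
  line_fit <- stats::lm(log_ptau ~ egfr, weights = w)
  sse_line <- wsse(line_fit)

  best <- NULL
  best_sse <- Inf
  tie <- FALSE
  for (psi in candidates) {
    hinge <- pmax(egfr - psi, 0)
    fit <- stats::lm(log_ptau ~ egfr + hinge, weights = w)
    s <- wsse(fit)
    if (s < best_sse - 1e-12) {
      best_sse <- s
      best <- list(psi = psi, coef = stats::coef(fit))
      tie <- FALSE
    } else if (abs(s - best_sse) <= 1e-12) {
      tie <- TRUE  # keep the earlier (smaller) psi
    }
  }
  co <- best$coef
  co[is.na(co)] <- 0  # hinge collinear with egfr at extreme psi
  structure(list(psi = best$psi,
                 intercept = unname(co[1]),
                 slope_left = unname(co["egfr"]),
                 slope_right = unname(co["egfr"] + co["hinge"]),
                 sse = best_sse, sse_line = sse_line,
                 resolution = resolution, tie = tie, n = length(egfr)),
            class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf(
    "Segmented fit: breakpoint %.2f; slopes %.4f (below) / %.4f (above); weighted SSE %.4g (line: %.4g); n = %d\n",
    x$psi, x$slope_left, x$slope_right, x$sse, x$sse_line, x$n))
  if (x$tie) cat("note: SSE tie at grid resolution; smallest breakpoint kept\n")
  invisible(x)
}

#' Predict from a segmented fit on the original concentration scale
#'
#' Evaluates the continuous two-segment mean of log pTau217 on an eGFR grid
#' and exponentiates back to pg/ml.
#'
#' @param fit A `segmented_fit`.
#' @param egfr Numeric eGFR grid.
#' @return Data frame `egfr`, `fitted_ptau217` (pg/ml), `segment`
#'   (`"below"`/`"above"` the breakpoint).
#' @export
predict_segmented <- function(fit, egfr) {
  stopifnot(inherits(fit, "segmented_fit"))
  mu <- fit$intercept + fit$slope_left * pmin(egfr, fit$psi) +
    fit$slope_right * pmax(egfr - fit$psi, 0)
  data.frame(egfr = egfr, fitted_ptau217 = exp(mu),
             segment = ifelse(egfr < fit$psi, "below", "above"))
}
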