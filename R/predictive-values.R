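# Bayes predictive-value sensitivity analysis.
#
# PPV and NPV are prevalence-dependent; with externally reported ranges of
# sensitivity and specificity the analysis enumerates every (Se, Sp) pair on
# a fixed-step grid, evaluates both predictive values at the stratum's
# weighted prevalence, and summarizes the resulting empirical distributions
# by their median and 2.5th/97.5th percentiles. Optimism correction shrinks
# Se and Sp toward chance (0.5) before the Bayes computation.

#' Positive predictive value
#'
#' `PPV = Se * Prev / (Se * Prev + (1 - Sp) * (1 - Prev))`.
#'
#' @param se Sensitivity in `[0,1]`.
#' @param sp Specificity in `[0,1]`.
#' @param prev Prevalence in `[0,1]`.
#' @return PPV in `[0,1]`. Vectorized; errors on a zero denominator.
#' @export
ppv <- function(se, sp, prev) {
  .check_unit(se, sp, prev)
  denom <- se * prev + (1 - sp) * (1 - prev)
  if (any(denom == 0)) stop("PPV undefined: denominator is zero",
                            call. = FALSE)
  se * prev / denom
}

#' Negative predictive value
#'
#' `NPV = Sp * (1 - Prev) / ((1 - Se) * Prev + Sp * (1 - Prev))`.
#'
#' @inheritParams ppv
#' @return NPV in `[0,1]`. Vectorized; errors on a zero denominator.
#' @export
npv <- function(se, sp, prev) {
  .check_unit(se, sp, prev)
  denom <- (1 - se) * prev + sp * (1 - prev)
  if (any(denom == 0)) stop("NPV undefined: denominator is zero",
                            call. = FALSE)
  sp * (1 - prev) / denom
}

.check_unit <- function(...) {
  for (x in list(...)) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
      stop("sensitivity, specificity and prevalence must lie in [0,1]",
           call. = FALSE)
    }
  }
}

#' Optimism shrinkage toward chance
#'
#' Affine contraction of a sensitivity or specificity toward 0.5:
#' `x' = 0.5 + lambda * (x - 0.5)`. At `lambda = 1` the value is unchanged;
#' smaller `lambda` pulls the operating characteristics toward an
#' uninformative test, anticipating degraded performance on new cohorts.
#'
#' @param x Proportion(s) in `[0,1]`.
#' @param lambda Shrinkage level in `(0, 1]`.
#' @return Shrunken proportion(s).
#' @export
shrink_toward_chance <- function(x, lambda) {
  .check_unit(x)
  stopifnot(length(lambda) == 1L, lambda > 0, lambda <= 1)
  if (lambda == 1) return(x)  # exact identity at no shrinkage
  0.5 + lambda * (x - 0.5)
}

#' Sensitivity/specificity enumeration grid
#'
#' Closed ranges of sensitivity and specificity enumerated at a fixed step.
#' Grid coordinates are built by integer index from the lower bound and
#' rounded to the step's precision, so no floating-point drift accumulates.
#' The defaults (Se 0.850-0.982, Sp 0.745-0.986, step 0.001) give a
#' 133 x 242 grid.
#'
#' @param se_min,se_max Sensitivity bounds (inclusive).
#' @param sp_min,sp_max Specificity bounds (inclusive).
#' @param step Grid increment.
#' @return Object of class `diagnostic_grid` with vectors `se` and `sp`.
#' @export
diagnostic_grid <- function(se_min = 0.850, se_max = 0.982,
                            sp_min = 0.745, sp_max = 0.986,
                            step = 0.001) {
  stopifnot(step > 0, se_min > 0, sp_min > 0,
            se_min <= se_max, sp_min <= sp_max, se_max <= 1, sp_max <= 1)
  digits <- max(0L, ceiling(-log10(step)))
  idx <- function(lo, hi) {
    round(lo + step * seq.int(0L, floor((hi - lo) / step + 1e-9)), digits)
  }
  structure(list(se = idx(se_min, se_max), sp = idx(sp_min, sp_max),
                 step = step),
            class = "diagnostic_grid")
}

#' Predictive-value summary over the diagnostic grid
#'
#' Enumerates every (Se, Sp) pair on the grid, optionally shrinks both
#' coordinates toward chance, evaluates PPV and NPV at the given
#' prevalence, and summarizes each empirical distribution with the median
#' and the 2.5th and 97.5th percentiles (linear interpolation between order
#' statistics, `stats::quantile` type 7). Order-independent by
#' construction.
#'
#' @param prevalence Prevalence in `(0,1)`.
#' @param grid A [diagnostic_grid()].
#' @param lambda Shrinkage level in `(0,1]`; 1 means no shrinkage.
#' @return Data frame of class `pv_summary`: one row per measure
#'   (`ppv`, `npv`) with `median`, `p2.5`, `p97.5`, `prevalence`,
#'   `lambda`, `n_grid`.
#' @export
grid_summary <- function(prevalence, grid = diagnostic_grid(),
                         lambda = 1) {
  stopifnot(inherits(grid, "diagnostic_grid"))
  if (length(grid$se) == 0L || length(grid$sp) == 0L) {
    stop("empty diagnostic grid", call. = FALSE)
  }
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie strictly within (0,1)", call. = FALSE)
  }
  pairs <- expand.grid(se = grid$se, sp = grid$sp,
                       KEEP.OUT.ATTRS = FALSE)
  se <- shrink_toward_chance(pairs$se, lambda)
  sp <- shrink_toward_chance(pairs$sp, lambda)
  pv <- list(ppv = ppv(se, sp, prevalence),
             npv = npv(se, sp, prevalence))
  out <- do.call(rbind, lapply(names(pv), function(m) {
    q <- stats::quantile(pv[[m]], c(0.025, 0.5, 0.975), names = FALSE,
                         type = 7)
    data.frame(measure = m, median = q[2], p2.5 = q[1], p97.5 = q[3],
               prevalence = prevalence, lambda = lambda,
               n_grid = nrow(pairs), stringsAsFactors = FALSE)
  }))
  class(out) <- c("pv_summary", class(out))
  out
}

#' Predictive-value sweep across strata
#'
#' Runs [grid_summary()] at each stratum's prevalence (plus an optional
#' overall prevalence supplied under the name `"overall"`). Because PPV is
#' increasing and NPV decreasing in prevalence, strata with higher
#' prevalence get higher median PPV and lower median NPV.
#'
#' @param prevalences Named numeric vector of stratum prevalences, each
#'   strictly in `(0,1)`.
#' @param grid A [diagnostic_grid()].
#' @param lambda Shrinkage level in `(0,1]`.
#' @return Data frame: one row per stratum x measure with the
#'   [grid_summary()] columns plus `stratum`.
#' @export
stratum_sweep <- function(prevalences, grid = diagnostic_grid(),
                          lambda = 1) {
  if (is.null(names(prevalences)) || any(!nzchar(names(prevalences)))) {
    stop("prevalences must be a named vector", call. = FALSE)
  }
  if (any(prevalences <= 0) || any(prevalences >= 1)) {
    stop("stratum prevalences must lie strictly within (0,1)",
         call. = FALSE)
  }
  out <- do.call(rbind, lapply(names(prevalences), function(s) {
    cbind(stratum = s,
          grid_summary(prevalences[[s]], grid = grid, lambda = lambda),
          stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
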