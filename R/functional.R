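#' Normalized transendothelial electrical resistance
#'
#' The background resistance of the blank filter is subtracted from the raw
#' monolayer reading and the result is multiplied by the effective filter
#' area, giving the monolayer resistance in ohm cm^2.
#'
#' @param raw_ohm measured resistance(s), ohm.
#' @param blank_ohm blank-filter resistance(s), ohm.
#' @param area_cm2 effective filter area, cm^2 (default 0.33, a 12-well
#'   Transwell insert).
#' @return Numeric vector `(raw_ohm - blank_ohm) * area_cm2`. Values where
#'   the raw reading fell below the blank are returned negative with a
#'   warning, never silently dropped.
#' @examples
#' compute_ter(160.09, 121)   # 12.9 ohm cm^2
#' @export
compute_ter <- function(raw_ohm, blank_ohm, area_cm2 = 0.33) {
  stopifnot(all(raw_ohm >= 0), all(area_cm2 > 0))
  ter <- (raw_ohm - blank_ohm) * area_cm2
  if (any(ter < 0))
    warning(sprintf("%d TER value(s) below the blank resistance (negative TER, flagged)",
                    sum(ter < 0)))
  ter
}

#' TER fold change relative to control
#'
#' The treated ratio `ter_t / ter_initial` normalized (divided) by the mean
#' control ratio of the same experiment.
#'
#' @param ter_t TER at the evaluation timepoint (ohm cm^2).
#' @param ter_initial baseline TER (ohm cm^2).
#' @param control_ratio mean `ter_t / ter_initial` of the control group.
#' @return `(ter_t / ter_initial) / control_ratio`.
#' @export
ter_fold_change <- function(ter_t, ter_initial, control_ratio = 1) {
  if (any(ter_initial <= 0)) stop("ter_initial must be positive")
  if (any(control_ratio <= 0)) stop("control_ratio must be positive")
  (ter_t / ter_initial) / control_ratio
}

#' Recover TER fold changes from a measurement table
#'
#' Applies [compute_ter()] to every reading, forms the per-replicate ratio
#' `TER(t) / TER(0)`, and normalizes treated ratios by the mean control
#' ratio via [ter_fold_change()].
#'
#' @param ter data.frame as produced by [generate_functional_dataset()]
#'   (`condition`, `replicate`, `timepoint_h`, `raw_ohm`, `blank_ohm`,
#'   `area_cm2`).
#' @param timepoint_h evaluation timepoint.
#' @param control control condition label.
#' @return List with `fold_changes` (per treated replicate), `mean_fold`,
#'   `sd_fold`, `control_ratio` and the raw per-replicate `control_ratios`
#'   and `treated_ratios`.
#' @export
recover_ter_fold <- function(ter, timepoint_h, control = "control") {
  ter$ter <- compute_ter(ter$raw_ohm, ter$blank_ohm, ter$area_cm2)
  base <- ter[ter$timepoint_h == 0, ]
  at_t <- ter[ter$timepoint_h == timepoint_h, ]
  key <- function(d) paste(d$condition, d$replicate)
  ratio <- at_t$ter / base$ter[match(key(at_t), key(base))]
  is_ctrl <- at_t$condition == control
  if (!any(is_ctrl) || all(is_ctrl))
    stop("need both control and treated measurements")
  control_ratio <- mean(ratio[is_ctrl])
  folds <- ter_fold_change(at_t$ter[!is_ctrl],
                           base$ter[match(key(at_t[!is_ctrl, ]), key(base))],
                           control_ratio)
  list(fold_changes = folds, mean_fold = mean(folds), sd_fold = sd(folds),
       control_ratio = control_ratio, control_ratios = ratio[is_ctrl],
       treated_ratios = ratio[!is_ctrl])
}

#' Calibrate the fluorimeter and quantify tracer flux
#'
#' Fits an ordinary least-squares calibration line `AU = slope * conc +
#' intercept` to the standards, converts sample fluorescence readings to
#' tracer concentrations, and expresses each treated condition's mean
#' concentration as percent of the control mean.
#'
#' @param standards data.frame with columns `conc_mg_ml` and
#'   `fluorescence_au` (>= 2 distinct concentrations).
#' @param samples data.frame with columns `condition` and `fluorescence_au`.
#' @param control control condition label.
#' @return List with `curve` (slope, intercept, r_squared), `samples` (input
#'   plus `conc_mg_ml`) and `percent_of_control` (named vector, one entry per
#'   non-control condition). Negative inferred concentrations are clipped to
#'   zero with a warning.
#' @export
calibrate_and_quantify_flux <- function(standards, samples,
                                        control = "control") {
  if (length(unique(standards$conc_mg_ml)) < 2)
    stop("degenerate standards: need at least 2 distinct concentrations")
  fit <- lm(fluorescence_au ~ conc_mg_ml, data = standards)
  slope <- coef(fit)[["conc_mg_ml"]]
  intercept <- coef(fit)[["(Intercept)"]]
  if (slope <= 0) stop("calibration slope must be positive")
  sst <- sum((standards$fluorescence_au - mean(standards$fluorescence_au))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  conc <- (samples$fluorescence_au - intercept) / slope
  if (any(conc < 0)) {
    warning(sprintf("%d inferred concentration(s) were negative; clipped to 0",
                    sum(conc < 0)))
    conc[conc < 0] <- 0
  }
  samples$conc_mg_ml <- conc
  if (!control %in% samples$condition)
    stop(sprintf("control condition '%s' not present in samples", control))
  ctrl_mean <- mean(conc[samples$condition == control])
  others <- setdiff(unique(samples$condition), control)
  pct <- vapply(others, function(cn) {
    100 * mean(conc[samples$condition == cn]) / ctrl_mean
  }, numeric(1))
  list(curve = list(slope = slope, intercept = intercept, r_squared = r2),
       samples = samples, percent_of_control = pct)
}

#' Compare two groups with a two-sided Student's t-test
#'
#' Classical equal-variance two-sample t-test, reporting group means and SDs
#' alongside the statistic and two-sided p-value. Degenerate zero-variance
#' inputs are handled explicitly: identical means give `p = 1`, different
#' means with zero pooled variance give `p = 0` with a flag.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return List with `mean_a`, `sd_a`, `mean_b`, `sd_b`, `t`, `p` and
#'   `flagged` (TRUE when the zero-variance degenerate path was taken).
#' @export
compare_conditions <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  out <- list(mean_a = mean(a), sd_a = sd(a), mean_b = mean(b), sd_b = sd(b))
  pooled <- sqrt(((length(a) - 1) * sd(a)^2 + (length(b) - 1) * sd(b)^2) /
                   (length(a) + length(b) - 2))
  if (pooled == 0) {
    if (mean(a) == mean(b)) {
      out$t <- 0; out$p <- 1; out$flagged <- FALSE
    } else {
      out$t <- sign(mean(a) - mean(b)) * Inf; out$p <- 0; out$flagged <- TRUE
      warning("zero pooled variance with unequal means; p -> 0 (flagged)")
    }
  } else {
    tt <- t.test(a, b, var.equal = TRUE)
    out$t <- unname(tt$statistic); out$p <- tt$p.value; out$flagged <- FALSE
  }
  out
}
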