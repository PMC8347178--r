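# lognormal multiplicative noise with mean 1 and coefficient of variation cv
lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(rnorm(n, -s2 / 2, sqrt(s2)))
}

#' Generate a synthetic barrier-function dataset
#'
#' Emulates a Transwell TER + tracer-flux experiment with a tightening
#' treatment: control TER trajectories stay flat around the baseline, treated
#' trajectories are multiplied by `ter_fold_1h` / `ter_fold_5h` at the 1 h and
#' 5 h timepoints, and the treated basolateral tracer concentration is
#' `flux_fraction_of_control` times the control one. Raw resistances include
#' the substrate blank so downstream blank subtraction is exercised, and
#' fluorescence readings are synthesized through a known calibration line so
#' downstream curve fitting is exercised. Every measurement carries
#' independent lognormal noise of coefficient of variation `replicate_cv`
#' (mean-preserving), so `replicate_cv = 0` reproduces the effect parameters
#' exactly.
#'
#' @param effects an [effect_params()].
#' @param n_replicates replicates per condition (>= 3).
#' @param seed integer RNG seed.
#' @param substrate `"PE"` or `"PC"` (selects the blank resistance).
#' @param conditions length-2 character: control label then treated label.
#' @return List of data.frames: `ter` (`condition`, `replicate`,
#'   `timepoint_h`, `raw_ohm`, `blank_ohm`, `area_cm2`, `substrate`), `flux`
#'   (`condition`, `replicate`, `compartment`, `timepoint_h`,
#'   `fluorescence_au`) and `standards` (`conc_mg_ml`, `fluorescence_au`).
#' @export
generate_functional_dataset <- function(effects = effect_params(),
                                        n_replicates = 6L, seed = 1L,
                                        substrate = c("PE", "PC"),
                                        conditions = c("control", "treated")) {
  stopifnot(inherits(effects, "effect_params"), n_replicates >= 3)
  substrate <- match.arg(substrate)
  set.seed(seed)
  blank <- effects$blank_ohm[[substrate]]
  cv <- effects$replicate_cv
  timepoints <- c(0, 1, 5)
  fold <- rbind(control = c(1, 1, 1),
                treated = c(1, effects$ter_fold_1h, effects$ter_fold_5h))

  ter <- do.call(rbind, lapply(1:2, function(ci) {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      true_ter <- effects$baseline_ter_ohm_cm2 * fold[ci, ] *
        lognoise(length(timepoints), cv)
      data.frame(condition = conditions[ci], replicate = r,
                 timepoint_h = timepoints,
                 raw_ohm = true_ter / effects$area_cm2 + blank,
                 blank_ohm = blank, area_cm2 = effects$area_cm2,
                 substrate = substrate)
    }))
  }))

  base_conc <- 0.02                       # control basolateral conc, mg/mL
  conc <- c(base_conc * lognoise(n_replicates, cv),
            base_conc * effects$flux_fraction_of_control *
              lognoise(n_replicates, cv))
  flux <- data.frame(
    condition = rep(conditions, each = n_replicates),
    replicate = rep(seq_len(n_replicates), 2),
    compartment = "basolateral", timepoint_h = 5,
    fluorescence_au = effects$cal_intercept_au +
      effects$cal_slope_au_per_mg_ml * conc)

  std_conc <- c(0, 0.005, 0.01, 0.02, 0.05, 0.1)
  standards <- data.frame(
    conc_mg_ml = std_conc,
    fluorescence_au = effects$cal_intercept_au +
      effects$cal_slope_au_per_mg_ml * std_conc)

  list(ter = ter, flux = flux, standards = standards)
}
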