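#' Fluorophore placement parameters
#'
#' Controls how labelled molecules are distributed along the junction belts:
#' `"dispersed"` places them uniformly along the belt arc length, modelling a
#' loosely organized junction; `"clustered"` places Thomas-process clusters
#' (parents uniform on the belt, offspring counts Poisson, isotropic Gaussian
#' scatter), modelling the short-range molecular clustering of a tightened
#' claudin-5 belt.
#'
#' @param mode `"dispersed"` or `"clustered"`.
#' @param linear_density_per_um expected molecules per micrometre of belt.
#' @param cluster_sigma_nm within-cluster Gaussian spread (nm); required for
#'   clustered mode.
#' @param mean_molecules_per_cluster mean offspring count per cluster parent.
#' @param off_belt_fraction fraction of molecules placed uniformly over the
#'   whole field (non-junctional background labelling), in `[0, 1)`.
#' @return An object of class `clustering_params`.
#' @export
clustering_params <- function(mode = c("dispersed", "clustered"),
                              linear_density_per_um = 10,
                              cluster_sigma_nm = 20,
                              mean_molecules_per_cluster = 5,
                              off_belt_fraction = 0) {
  mode <- match.arg(mode)
  stopifnot(linear_density_per_um > 0,
            off_belt_fraction >= 0, off_belt_fraction < 1,
            mean_molecules_per_cluster > 0)
  if (mode == "clustered") stopifnot(cluster_sigma_nm > 0)
  structure(list(mode = mode,
                 linear_density_per_um = linear_density_per_um,
                 cluster_sigma_nm = cluster_sigma_nm,
                 mean_molecules_per_cluster = mean_molecules_per_cluster,
                 off_belt_fraction = off_belt_fraction),
            class = "clustering_params")
}

#' SMLM acquisition parameters
#'
#' Defaults mirror a typical EMCCD single-molecule acquisition: 2000 frames at
#' 80 nm/px with EM gain 100. The point-spread function is an integrated
#' symmetric Gaussian; the camera model is Poisson photon shot noise scaled by
#' the EM gain, plus Gaussian read noise and a constant baseline offset.
#'
#' @param n_frames number of movie frames.
#' @param pixel_nm camera pixel pitch (nm).
#' @param psf_sigma_nm Gaussian PSF standard deviation (nm). The default
#'   130 nm is typical for a 1.46 NA objective at 561-642 nm excitation.
#' @param photons_per_on_frame mean photons emitted per fluorophore per ON
#'   frame.
#' @param on_probability per-frame, per-fluorophore probability of being in
#'   the emissive state (independent Bernoulli blinking).
#' @param em_gain electron-multiplying gain (ADU per photo-electron).
#' @param read_noise_adu Gaussian read noise SD (ADU).
#' @param baseline_adu constant camera offset (ADU).
#' @param shot_noise logical; disable to render the noise-free expected image
#'   (used for photon-conservation checks).
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(n_frames = 2000L, pixel_nm = 80,
                               psf_sigma_nm = 130,
                               photons_per_on_frame = 500,
                               on_probability = 0.005,
                               em_gain = 100, read_noise_adu = 10,
                               baseline_adu = 100, shot_noise = TRUE) {
  stopifnot(n_frames >= 1, pixel_nm > 0, psf_sigma_nm > 0,
            photons_per_on_frame > 0, on_probability >= 0, on_probability < 1,
            em_gain > 0, read_noise_adu >= 0, baseline_adu >= 0)
  structure(list(n_frames = as.integer(n_frames), pixel_nm = pixel_nm,
                 psf_sigma_nm = psf_sigma_nm,
                 photons_per_on_frame = photons_per_on_frame,
                 on_probability = on_probability, em_gain = em_gain,
                 read_noise_adu = read_noise_adu, baseline_adu = baseline_adu,
                 shot_noise = isTRUE(shot_noise), bit_depth = 16L),
            class = "acquisition_params")
}

#' Spot detection and fitting parameters
#'
#' `threshold_factor = 3` with `discard_frames = 30` reproduces the standard
#' SMLM noise-reduction recipe: the first 30 frames of each time-stack (still
#' contaminated by the initial bleach-down) are discarded, and candidate
#' pixels must exceed the robust per-frame background by three robust noise
#' standard deviations.
#'
#' @param discard_frames number of initial frames to discard.
#' @param threshold_factor detection threshold in robust noise SDs above
#'   the robust background level.
#' @param fit_window_px odd fit window edge length (>= 5 px).
#' @param psf_sigma_nm nominal PSF sigma (nm) used to initialize fits and to
#'   bound accepted widths to `[0.5, 3]` times nominal.
#' @param smooth_sigma_px Gaussian pre-filter SD (px) applied before
#'   candidate detection (matched filtering); 0 disables. The threshold is
#'   still expressed in raw-frame robust noise SDs, so single-pixel noise
#'   excursions are strongly suppressed while PSF-sized spots survive.
#' @param max_iterations,convergence_tol Levenberg-Marquardt controls.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(discard_frames = 30L, threshold_factor = 3,
                             fit_window_px = 9L, psf_sigma_nm = 130,
                             smooth_sigma_px = 1,
                             max_iterations = 100L, convergence_tol = 1e-8) {
  stopifnot(discard_frames >= 0, threshold_factor > 0, fit_window_px >= 5,
            fit_window_px %% 2 == 1, psf_sigma_nm > 0, smooth_sigma_px >= 0)
  structure(list(discard_frames = as.integer(discard_frames),
                 threshold_factor = threshold_factor,
                 fit_window_px = as.integer(fit_window_px),
                 psf_sigma_nm = psf_sigma_nm,
                 smooth_sigma_px = smooth_sigma_px,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol),
            class = "detection_params")
}

#' Treatment effect parameters for the functional-data generator
#'
#' Defaults encode a barrier-tightening dipeptide treatment of an endothelial
#' monolayer: transendothelial resistance rises by a factor 1.30 after 1 h and
#' 1.41 after 5 h relative to medium control, while 10 kDa dextran flux falls
#' to 31.7% of control. Blank-filter resistances differ by substrate
#' (polyester 121 ohm, polycarbonate 88 ohm) while the blank-corrected
#' baseline is about 12.9 ohm cm^2.
#'
#' @param ter_fold_1h,ter_fold_5h treated/control TER fold change at 1 h / 5 h.
#' @param flux_fraction_of_control treated basolateral tracer concentration as
#'   a fraction of control.
#' @param replicate_cv lognormal coefficient of variation applied per
#'   measurement.
#' @param baseline_ter_ohm_cm2 blank-corrected baseline TER (ohm cm^2).
#' @param blank_ohm named vector of blank-filter resistances per substrate.
#' @param area_cm2 effective filter area (cm^2).
#' @param cal_slope_au_per_mg_ml,cal_intercept_au fluorimeter calibration line
#'   used to synthesize fluorescence readings from tracer concentrations.
#' @return An object of class `effect_params`.
#' @export
effect_params <- function(ter_fold_1h = 1.30, ter_fold_5h = 1.41,
                          flux_fraction_of_control = 0.317,
                          replicate_cv = 0.1,
                          baseline_ter_ohm_cm2 = 12.9,
                          blank_ohm = c(PE = 121, PC = 88),
                          area_cm2 = 0.33,
                          cal_slope_au_per_mg_ml = 2000,
                          cal_intercept_au = 10) {
  stopifnot(ter_fold_1h > 0, ter_fold_5h > 0,
            flux_fraction_of_control > 0, flux_fraction_of_control <= 1,
            replicate_cv >= 0, baseline_ter_ohm_cm2 > 0, all(blank_ohm > 0),
            area_cm2 > 0, cal_slope_au_per_mg_ml > 0)
  structure(list(ter_fold_1h = ter_fold_1h, ter_fold_5h = ter_fold_5h,
                 flux_fraction_of_control = flux_fraction_of_control,
                 replicate_cv = replicate_cv,
                 baseline_ter_ohm_cm2 = baseline_ter_ohm_cm2,
                 blank_ohm = blank_ohm, area_cm2 = area_cm2,
                 cal_slope_au_per_mg_ml = cal_slope_au_per_mg_ml,
                 cal_intercept_au = cal_intercept_au),
            class = "effect_params")
}
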