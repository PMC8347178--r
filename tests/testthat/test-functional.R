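test_that("TER normalization reproduces the blank-subtraction arithmetic", {
  expect_equal(compute_ter(121, 121, 0.33), 0)
  expect_equal(signif(compute_ter(160.09, 121, 0.33), 3), 12.9)
  expect_equal(signif(compute_ter(128.0, 88, 0.33), 3), 13.2)
  # linear in the blank-corrected resistance and in the area
  expect_equal(compute_ter(300, 100, 0.33), 2 * compute_ter(200, 100, 0.33))
  expect_equal(compute_ter(150, 100, 0.66), 2 * compute_ter(150, 100, 0.33))
  expect_warning(flagged <- compute_ter(100, 121, 0.33), "below the blank")
  expect_lt(flagged, 0)
})

test_that("TER fold change is the treated ratio over the control ratio", {
  expect_equal(ter_fold_change(10, 10, 1), 1.0)
  expect_equal(ter_fold_change(13, 10, 1.0), 1.30)
  expect_equal(ter_fold_change(13, 10, 1.3), 1.0)
  expect_error(ter_fold_change(13, 0), "positive")
  expect_error(ter_fold_change(13, 10, 0), "positive")
})

test_that("noise-free generated data returns the effect parameters exactly", {
  eff <- effect_params(replicate_cv = 0)
  ds <- generate_functional_dataset(eff, n_replicates = 4, seed = 1)
  f1 <- recover_ter_fold(ds$ter, 1)
  f5 <- recover_ter_fold(ds$ter, 5)
  expect_equal(f1$mean_fold, 1.30, tolerance = 1e-12)
  expect_equal(f5$mean_fold, 1.41, tolerance = 1e-12)
  fl <- calibrate_and_quantify_flux(ds$standards, ds$flux)
  expect_equal(unname(fl$percent_of_control["treated"]), 31.7,
               tolerance = 1e-9)
  expect_equal(fl$curve$r_squared, 1)
  # raw resistances include the substrate blank
  expect_true(all(ds$ter$raw_ohm > ds$ter$blank_ohm))
})

test_that("the calibration line converts fluorescence to concentration", {
  standards <- data.frame(conc_mg_ml = c(0, 1), fluorescence_au = c(0, 10))
  samples <- data.frame(condition = c("control", "treated"),
                        fluorescence_au = c(10, 5))
  res <- calibrate_and_quantify_flux(standards, samples)
  expect_equal(res$samples$conc_mg_ml, c(1, 0.5))
  expect_equal(unname(res$percent_of_control["treated"]), 50)
  # equal means give 100%
  same <- data.frame(condition = c("control", "treated"),
                     fluorescence_au = c(6, 6))
  expect_equal(unname(calibrate_and_quantify_flux(standards, same)$percent_of_control), 100)
  expect_error(calibrate_and_quantify_flux(
    data.frame(conc_mg_ml = c(1, 1), fluorescence_au = c(5, 6)), samples),
    "degenerate")
  expect_warning(calibrate_and_quantify_flux(
    data.frame(conc_mg_ml = c(0, 1), fluorescence_au = c(5, 15)),
    data.frame(condition = c("control", "treated"),
               fluorescence_au = c(10, 1))), "negative")
})

test_that("percent of control is invariant to rescaling all fluorescence values", {
  standards <- data.frame(conc_mg_ml = c(0, 0.5, 1),
                          fluorescence_au = c(0, 5, 10))
  samples <- data.frame(condition = rep(c("control", "treated"), each = 3),
                        fluorescence_au = c(8, 9, 10, 3, 4, 5))
  p1 <- calibrate_and_quantify_flux(standards, samples)$percent_of_control
  standards2 <- standards; standards2$fluorescence_au <- standards$fluorescence_au * 7
  samples2 <- samples; samples2$fluorescence_au <- samples$fluorescence_au * 7
  p2 <- calibrate_and_quantify_flux(standards2, samples2)$percent_of_control
  expect_equal(p1, p2)
})

test_that("the group comparison matches the hand-computed t statistic", {
  res <- compare_conditions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  res <- compare_conditions(c(1, 2, 3), c(11, 12, 13))
  expect_equal(abs(res$t), 10 / sqrt(2 / 3), tolerance = 1e-12)
  expect_lt(res$p, 0.001)
  # degenerate zero-variance cases
  same <- compare_conditions(c(2, 2), c(2, 2))
  expect_equal(c(same$t, same$p), c(0, 1))
  expect_warning(zv <- compare_conditions(c(2, 2), c(3, 3)), "zero pooled")
  expect_equal(zv$p, 0)
  expect_true(zv$flagged)
})

test_that("the t-test holds its nominal type-I error rate under the null", {
  set.seed(1234)
  rejections <- vapply(1:10000, function(i) {
    compare_conditions(rnorm(5), rnorm(5))$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.01)
})

test_that("recovery converges to the generator parameters with many replicates", {
  eff <- effect_params(replicate_cv = 0.1)
  ds <- generate_functional_dataset(eff, n_replicates = 100, seed = 7)
  f1 <- recover_ter_fold(ds$ter, 1)
  expect_lt(abs(f1$mean_fold - 1.30), 0.06)
  fl <- calibrate_and_quantify_flux(ds$standards, ds$flux)
  expect_lt(abs(fl$percent_of_control[["treated"]] - 31.7), 1.5)
})
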