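test_that("robust background estimation resists bright contamination", {
  const <- matrix(100, 32, 32)
  bg <- estimate_background(const)
  expect_equal(c(bg$bg_level, bg$noise_sd), c(100, 0))
  expect_true(bg$flagged)

  set.seed(21)
  noise <- matrix(rnorm(512^2, 500, 10), 512, 512)
  bg <- estimate_background(noise)
  expect_lt(abs(bg$bg_level - 500) / 500, 0.01)
  expect_lt(abs(bg$noise_sd - 10) / 10, 0.01)

  contaminated <- noise
  contaminated[sample(length(noise), 10)] <- 50000    # 10 bright spots
  bg2 <- estimate_background(contaminated)
  expect_lt(abs(bg2$bg_level - 500) / 500, 0.01)
})

test_that("candidate detection finds spots and stays quiet on blank frames", {
  params <- detection_params(psf_sigma_nm = 130)
  expect_equal(nrow(detect_candidates(matrix(0, 64, 64), params)), 0)

  # noiseless single spot, amplitude 10x an assumed noise floor
  frame <- sampled_gaussian_frame(41, 41, 20.5, 20.5, 100, 1.6, offset = 10)
  cand <- detect_candidates(frame, params,
                            background = list(bg_level = 10, noise_sd = 10))
  expect_equal(nrow(cand), 1)
  expect_equal(unname(cand[1, ]), c(21, 21))
})

test_that("detection at amplitude 6x noise has high recall and few false positives", {
  set.seed(77)
  params <- detection_params(psf_sigma_nm = 130)
  centers <- expand.grid(row = seq(10, 120, by = 14), col = seq(10, 120, by = 14))
  centers <- centers[sample(nrow(centers), 50), ]
  frame <- matrix(rnorm(128^2, 100, 10), 128, 128)
  for (k in seq_len(50))
    frame <- frame + sampled_gaussian_frame(128, 128, centers$col[k] - 0.5,
                                            centers$row[k] - 0.5, 60, 1.6)
  cand <- detect_candidates(frame, params)
  d <- sqrt(outer(cand[, "row"], centers$row, "-")^2 +
              outer(cand[, "col"], centers$col, "-")^2)
  recall <- mean(apply(d, 2, min) <= 2)
  false_pos <- sum(apply(d, 1, min) > 2)
  expect_gte(recall, 0.95)
  expect_lte(false_pos, 2)
})

test_that("noiseless Gaussian spots are refit to sub-millipixel accuracy", {
  params <- detection_params(psf_sigma_nm = 130, fit_window_px = 9)
  frame <- sampled_gaussian_frame(21, 21, 10.30, 7.75, 1000, 130 / 80,
                                  offset = 50)
  res <- fit_gaussian_2d(frame, c(8, 11), params, pixel_nm = 80)
  expect_false(is.null(res$record))
  expect_lt(abs(res$record$x_nm / 80 - 10.30), 1e-3)
  expect_lt(abs(res$record$y_nm / 80 - 7.75), 1e-3)
  expect_lt(abs(res$record$sigma_nm - 130), 130 * 1e-3)
  expect_equal(res$record$err_x_nm, res$record$err_y_nm, tolerance = 1e-6)
  expect_equal(res$record$amplitude, 1000, tolerance = 1e-3)
  expect_equal(res$record$offset, 50, tolerance = 1e-3)
})

test_that("implausible fits are rejected with reason codes", {
  params <- detection_params(psf_sigma_nm = 130)
  # a flat frame cannot produce a significant emitter
  flat <- matrix(100, 21, 21)
  res <- fit_gaussian_2d(flat, c(11, 11), params, 80, noise_sd = 10)
  expect_null(res$record)
  # a spot far wider than the PSF is rejected
  wide <- sampled_gaussian_frame(31, 31, 15.5, 15.5, 500, 8, offset = 100)
  res <- fit_gaussian_2d(wide, c(16, 16), params, 80)
  expect_identical(res$reason, "sigma_out_of_range")
  expect_error(fit_gaussian_2d(flat, c(1, 1), params, 80), "inside the frame")
})

make_test_stack <- function(n_frames = 60, seed = 3, on_probability = 0.03) {
  # belt inset from the field border so fit windows always fit
  g <- junction_geometry(list(matrix(c(600, 1000, 2400, 1000), 2, 2,
                                     byrow = TRUE)),
                         c(3000, 2000), n_cells = 2L)
  mol <- place_fluorophores(
    g, clustering_params("dispersed", linear_density_per_um = 6), seed = seed)
  render_smlm_stack(mol, acquisition_params(n_frames = n_frames,
                                            on_probability = on_probability),
                    seed = seed + 1)
}

test_that("the first 30 frames are discarded and thresholds act monotonically", {
  st <- make_test_stack(n_frames = 80)
  tab <- suppressWarnings(localize_stack(st, detection_params()))
  expect_true(all(tab$frame > 30))
  counts <- vapply(c(2, 3, 6), function(tf) {
    nrow(suppressWarnings(localize_stack(st, detection_params(threshold_factor = tf))))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(localize_stack(st, detection_params(discard_frames = 100)),
               "discard")
})

test_that("an all-background stack yields an empty localization table", {
  g <- straight_belt_geometry(3, 2)
  mol <- place_fluorophores(
    g, clustering_params("dispersed", linear_density_per_um = 6), seed = 1)
  st <- render_smlm_stack(mol, acquisition_params(n_frames = 35,
                                                  on_probability = 0),
                          seed = 2)
  tab <- localize_stack(st, detection_params())
  expect_equal(nrow(tab), 0)
})

test_that("localization counts track true ON events at high SNR", {
  st <- make_test_stack(n_frames = 300, seed = 11, on_probability = 0.01)
  tab <- suppressWarnings(localize_stack(st, detection_params()))
  ev <- attr(st, "on_events")
  n_events <- sum(ev$frame > 30)
  expect_gt(n_events, 20)
  expect_lt(abs(nrow(tab) - n_events) / n_events, 0.15)
})

test_that("localization is equivariant under integer-pixel translation", {
  st <- make_test_stack(n_frames = 45, seed = 5)
  d <- dim(st$data)
  shifted <- array(100, d + c(2, 2, 0))    # pad with the baseline level
  shifted[3:(d[1] + 2), 3:(d[2] + 2), ] <- st$data
  t1 <- suppressWarnings(localize_stack(st, detection_params()))
  t2 <- suppressWarnings(localize_stack(image_stack(shifted, st$pixel_nm),
                                        detection_params()))
  # match records by frame; positions must shift by exactly 2 px = 160 nm
  k1 <- order(t1$frame, t1$x_nm); k2 <- order(t2$frame, t2$x_nm)
  expect_equal(nrow(t1), nrow(t2))
  expect_equal(t2$x_nm[k2], t1$x_nm[k1] + 160, tolerance = 1e-6)
  expect_equal(t2$y_nm[k2], t1$y_nm[k1] + 160, tolerance = 1e-6)
})

test_that("ROI masking filters records and sets the analyzed area", {
  st <- make_test_stack(n_frames = 120, seed = 7)
  tab <- suppressWarnings(localize_stack(st, detection_params()))
  expect_gt(nrow(tab), 10)
  d <- dim(st$data)
  full <- roi_mask(matrix(TRUE, d[1], d[2]), st$pixel_nm)
  tf <- apply_mask(tab, full)
  expect_equal(nrow(tf), nrow(tab))
  expect_equal(attr(tf, "roi_area_nm2"), d[1] * d[2] * 80^2)
  expect_equal(loc_density(tf), nrow(tab) / (d[1] * d[2] * 80^2))

  # a mask whose single true pixel holds no localizations: empty table,
  # but the analyzed area is still well defined
  corner <- matrix(FALSE, d[1], d[2]); corner[1, 1] <- TRUE
  hit <- apply_mask(tab, roi_mask(corner, st$pixel_nm))
  expect_equal(nrow(hit), 0)
  expect_equal(attr(hit, "roi_area_nm2"), 80^2)
  expect_equal(loc_density(hit), 0)

  half <- roi_mask(cbind(matrix(TRUE, d[1], floor(d[2] / 2)),
                         matrix(FALSE, d[1], ceiling(d[2] / 2))),
                   st$pixel_nm)
  th <- apply_mask(tab, half)
  expect_true(all(th$x_nm < floor(d[2] / 2) * 80))
  expect_error(apply_mask(tab, roi_mask(matrix(FALSE, d[1], d[2]), 80)),
               "empty mask")
})

test_that("density requires a masked table", {
  tab <- loc_table(data.frame(frame = 31, x_nm = 100, y_nm = 100,
                              amplitude = 10, sigma_nm = 130, offset = 0,
                              err_x_nm = 5, err_y_nm = 5), pixel_nm = 80)
  expect_error(loc_density(tab), "unset")
})

test_that("pointillist rendering conserves counts and spacing", {
  recs <- data.frame(frame = c(31, 31), x_nm = c(105, 145), y_nm = c(55, 55),
                     amplitude = 10, sigma_nm = 130, offset = 0,
                     err_x_nm = 5, err_y_nm = 5)
  tab <- loc_table(recs, pixel_nm = 80)
  img <- render_pointillist(tab, 10, 0, field_size_nm = c(200, 100))
  expect_equal(sum(img), 2)
  nz <- which(img > 0, arr.ind = TRUE)
  expect_equal(abs(diff(nz[, "col"])), 4)      # 40 nm apart at 10 nm/px
  expect_equal(diff(nz[, "row"]), 0)
  one <- render_pointillist(loc_table(recs[1, ], pixel_nm = 80), 10, 0,
                            field_size_nm = c(200, 100))
  expect_equal(sum(one > 0), 1)
})
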