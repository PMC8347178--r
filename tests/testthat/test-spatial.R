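test_that("pair-distance histograms enumerate simple configurations exactly", {
  # two points 50 nm apart: all mass in bin [50, 60)
  h <- pairwise_distance_histogram(cbind(c(0, 50), c(0, 0)), 200, 10)
  expect_equal(h$rel_freq[6], 1)
  expect_equal(sum(h$rel_freq), 1)
  expect_equal(h$n_pairs, 1)

  # collinear points at 0, 30, 60 nm: distances {30, 30, 60}
  h <- pairwise_distance_histogram(cbind(c(0, 30, 60), c(0, 0, 0)), 200, 10)
  expect_equal(h$rel_freq[4], 2 / 3)
  expect_equal(h$rel_freq[7], 1 / 3)
  expect_error(pairwise_distance_histogram(cbind(1, 1)), "at least 2")
})

test_that("the spatial index reproduces the brute-force histogram", {
  set.seed(9)
  for (rep in 1:5) {
    n <- sample(500:2000, 1)
    xy <- cbind(runif(n, 0, 5000), runif(n, 0, 5000))
    h <- pairwise_distance_histogram(xy, 200, 10)
    expect_identical(as.numeric(h$counts),
                     as.numeric(brute_pair_counts(xy, 200, 10)))
  }
})

test_that("cross-channel histograms count ordered pairs", {
  h <- cross_pairwise_histogram(cbind(0, 0), cbind(100, 0), 400, 10)
  expect_equal(h$rel_freq[11], 1)            # bin [100, 110)
  # identical channels include the self-match zero-distance bin
  set.seed(2)
  xy <- cbind(runif(40, 0, 1000), runif(40, 0, 1000))
  h <- cross_pairwise_histogram(xy, xy, 400, 10)
  expect_equal(h$counts[1] >= 40, TRUE)
  expect_equal(as.numeric(h$counts), as.numeric(brute_cross_counts(xy, xy, 400, 10)))
  expect_error(cross_pairwise_histogram(xy[0, ], xy), "nonempty")
})

test_that("histograms are invariant to translation and rotation", {
  set.seed(4)
  xy <- cbind(runif(300, 0, 2000), runif(300, 0, 2000))
  h0 <- pairwise_distance_histogram(xy, 200, 10)
  ht <- pairwise_distance_histogram(xy + 5000, 200, 10)
  a <- pi / 7
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  hr <- pairwise_distance_histogram(xy %*% R + 3000, 200, 10)
  expect_equal(h0$rel_freq, ht$rel_freq)
  expect_equal(h0$rel_freq, hr$rel_freq, tolerance = 1e-12)
})

test_that("the CSR reference grows linearly at small distances in a square ROI", {
  roi <- roi_mask(matrix(TRUE, 100, 100), 100)    # 10 x 10 um square
  csr <- csr_reference(800, roi, r_max = 200, bin_width = 10, n_sim = 40,
                       seed = 2)
  # 2D CSR pair-distance density is ~ proportional to r for r << roi size:
  # bin centred at 15 nm should hold ~3x the mass of the bin at 5 nm, etc.
  centers <- (csr$bin_edges_nm[-1] + csr$bin_edges_nm[-21]) / 2
  fit <- lm(csr$mean ~ 0 + centers)
  rel_resid <- abs(csr$mean - fitted(fit)) / max(csr$mean)
  expect_lt(max(rel_resid), 0.15)
  expect_true(all(csr$lo <= csr$hi))
  # seeded determinism
  csr2 <- csr_reference(800, roi, r_max = 200, bin_width = 10, n_sim = 40,
                        seed = 2)
  expect_identical(csr, csr2)
})

test_that("a uniform sample falls inside its own CSR envelope almost everywhere", {
  roi <- roi_mask(matrix(TRUE, 80, 80), 100)
  csr <- csr_reference(500, roi, n_sim = 99, seed = 5)
  set.seed(31)
  cover <- replicate(10, {
    xy <- cbind(runif(500, 0, 8000), runif(500, 0, 8000))
    h <- pairwise_distance_histogram(xy, 200, 10)
    mean(h$rel_freq >= csr$lo & h$rel_freq <= csr$hi)
  })
  expect_gte(mean(cover), 0.95)
})

test_that("clustering excess compares the 40 nm bin against the CSR envelope", {
  roi <- roi_mask(matrix(TRUE, 50, 50), 100)
  csr <- csr_reference(200, roi, n_sim = 30, seed = 1)
  obs <- pairwise_distance_histogram(cbind(runif(200, 0, 5000),
                                           runif(200, 0, 5000)), 200, 10)
  # synthetic observation equal to the CSR mean: ratio 1, not clustered
  obs$rel_freq <- csr$mean
  cm <- clustering_excess(obs, csr, 40)
  expect_equal(cm$excess_ratio, 1)
  expect_false(cm$clustered)
  expect_equal(cm$r_eval_nm, 40)
  # bin mismatch is an error
  obs2 <- pairwise_distance_histogram(cbind(c(0, 50), c(0, 0)), 200, 20)
  expect_error(clustering_excess(obs2, csr), "do not match")
})

test_that("clustered placements are flagged and dispersed ones are not", {
  g <- generate_junction_network(5, c(12000, 12000), seed = 8)
  skeleton <- rasterize_belts(g, 10, 0)
  pc <- clustering_params("clustered", linear_density_per_um = 12,
                          cluster_sigma_nm = 20)
  pd <- clustering_params("dispersed", linear_density_per_um = 12)
  flags <- vapply(1:5, function(s) {
    mc <- place_fluorophores(g, pc, seed = s)
    md <- place_fluorophores(g, pd, seed = s + 100)
    cs <- csr_reference(nrow(mc), skeleton, n_sim = 49, seed = s)
    cd <- csr_reference(nrow(md), skeleton, n_sim = 49, seed = s + 100)
    c(clustering_excess(pairwise_distance_histogram(mc), cs)$clustered,
      clustering_excess(pairwise_distance_histogram(md), cd)$clustered)
  }, logical(2))
  expect_equal(sum(flags[1, ]), 5)     # every clustered seed flagged
  expect_lte(sum(flags[2, ]), 1)       # dispersed stays inside the envelope
})

test_that("colocalization matches brute force, is symmetric and monotone", {
  set.seed(12)
  xa <- cbind(runif(150, 0, 3000), runif(150, 0, 3000))
  xb <- cbind(runif(120, 0, 3000), runif(120, 0, 3000))
  res <- colocalize(xa, xb, 90)
  oracle <- brute_coloc_pct(xa, xb, 90)
  expect_equal(res$pct_A_coloc, unname(oracle["pct_A"]))
  expect_equal(res$pct_B_coloc, unname(oracle["pct_B"]))
  swapped <- colocalize(xb, xa, 90)
  expect_equal(res$pct_A_coloc, swapped$pct_B_coloc)
  expect_equal(res$pct_B_coloc, swapped$pct_A_coloc)
  pcts <- vapply(c(30, 60, 90, 150, 300), function(r) {
    colocalize(xa, xb, r)$pct_A_coloc
  }, numeric(1))
  expect_true(all(diff(pcts) >= 0))

  expect_equal(colocalize(xa, xa, 90)$pct_A_coloc, 100)
  far <- colocalize(cbind(0, 0), cbind(100, 0), 90)
  expect_equal(c(far$pct_A_coloc, far$pct_B_coloc), c(0, 0))
  near <- colocalize(cbind(0, 0), cbind(90, 0), 90)   # boundary is inclusive
  expect_equal(near$pct_A_coloc, 100)
  expect_error(colocalize(xa[0, , drop = FALSE], xb), "nonempty")
})
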