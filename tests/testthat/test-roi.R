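make_two_lung_fixture <- function(right_val = 66, left_val = 66,
                                  n_right = 1000, n_left = 500) {
  dims <- c(20, 15, 10)  # 3000 voxels
  labels <- array(0L, dims)
  labels[seq_len(n_right)] <- 1L
  labels[n_right + seq_len(n_left)] <- 2L
  t2 <- array(NA_real_, dims)
  t2[labels == 1L] <- right_val
  t2[labels == 2L] <- left_val
  list(map = fake_map(t2), mask = lung_mask(labels, c(3, 3, 3)))
}

test_that("ROI summaries: constant field, volumes and pooled-mean identity", {
  fx <- make_two_lung_fixture(66, 66)
  for (roi in c("right", "left", "both")) {
    sm <- summarize_roi(fx$map, fx$mask, roi)
    expect_equal(sm$mean_t2star, 66)
    expect_equal(sm$sd_t2star, 0)
  }
  # 1000 voxels at 3 mm isotropic = 27 mL
  expect_equal(summarize_roi(fx$map, fx$mask, "right")$volume_ml, 27.0)

  fx2 <- make_two_lung_fixture(60, 70)
  r <- summarize_roi(fx2$map, fx2$mask, "right")
  l <- summarize_roi(fx2$map, fx2$mask, "left")
  b <- summarize_roi(fx2$map, fx2$mask, "both")
  expect_equal(b$mean_t2star,
               (r$mean_t2star * r$n_voxels + l$mean_t2star * l$n_voxels) /
                 (r$n_voxels + l$n_voxels))
  expect_identical(b$n_voxels, r$n_voxels + l$n_voxels)
})

test_that("quality masks only shrink ROIs; empty ROI is flagged not fatal", {
  fx <- make_two_lung_fixture()
  full <- summarize_roi(fx$map, fx$mask, "both")
  q <- array(FALSE, dim(fx$mask$labels))
  q[fx$mask$labels == 1L] <- TRUE  # keep right lung only
  sub <- summarize_roi(fx$map, fx$mask, "both", quality = q)
  expect_lte(sub$n_voxels, full$n_voxels)
  none <- summarize_roi(fx$map, fx$mask, "left", quality = array(FALSE, dim(q)))
  expect_identical(none$n_voxels, 0L)
  expect_true(none$undefined)
  expect_true(is.na(none$mean_t2star))
})

test_that("ROI histograms partition the ROI voxels", {
  fx <- make_two_lung_fixture(66, 66)
  h <- roi_histogram(fx$map, fx$mask, "both", bins = 10)
  expect_identical(sum(h$counts), h$n_voxels)
  expect_identical(h$n_voxels, 1500L)
  # constant map: all mass in one bin
  expect_identical(sum(h$counts > 0), 1L)
  # two-valued map with two spanning bins: equal counts
  fx2 <- make_two_lung_fixture(50, 80, n_right = 500, n_left = 500)
  h2 <- roi_histogram(fx2$map, fx2$mask, "both", bins = c(40, 65, 90))
  expect_identical(h2$counts, c(500L, 500L))
  # empty ROI: all-zero counts
  labels <- array(0L, c(4, 4, 4)); labels[1:5] <- 1L
  m <- lung_mask(labels, c(3, 3, 3))
  h3 <- roi_histogram(fake_map(array(60, c(4, 4, 4))), m, "left", bins = 5)
  expect_true(all(h3$counts == 0L))
})

test_that("histogram spread tracks the generating texture SD on a phantom", {
  ph <- make_phantom(30, grid_shape = c(32, 28, 24),
                     tissues = default_tissues(30, lung_heterogeneity_sd = 0.1),
                     seed = 8)
  img <- simulate_multiecho(ph, noise_model = "none")
  map <- fit_map(img, mask = ph$label_map > 0, method = "loglinear")
  msk <- phantom_lung_mask(ph)
  sm <- summarize_roi(map, msk, "both")
  gen_sd <- 0.1 * normative_mean(published_model(), 30)
  expect_equal(sm$sd_t2star, gen_sd, tolerance = 0.15)
})

test_that("paired lung comparison handles identity, constant shift and power", {
  coh <- data.frame(scan_id = sprintf("s%02d", 1:20),
                    volume_ml_right = seq(20, 58, by = 2))
  coh$volume_ml_left <- coh$volume_ml_right
  same <- compare_lungs(coh, "volume_ml")
  expect_equal(same$mean_diff, 0)
  expect_equal(same$statistic, 0)
  expect_true(same$degenerate)

  coh$volume_ml_left <- coh$volume_ml_right - 5
  shift <- compare_lungs(coh, "volume_ml")
  expect_equal(shift$mean_diff, 5)
  expect_true(shift$degenerate)
  expect_lt(shift$p_value, 1e-300)

  # simulated cohort with left = 0.85 x right + noise: detected at n = 87
  set.seed(31)
  right <- rnorm(87, 40, 8)
  coh2 <- data.frame(scan_id = sprintf("s%02d", 1:87),
                     volume_ml_right = right,
                     volume_ml_left = 0.85 * right + rnorm(87, 0, 2))
  pw <- compare_lungs(coh2, "volume_ml")
  expect_lt(pw$p_value, 0.05)
  expect_gt(pw$mean_diff, 0)

  expect_error(compare_lungs(coh2[1, ], "volume_ml"), "pairs")
  expect_error(compare_lungs(coh2, "t2star_ms"), "columns")
})
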