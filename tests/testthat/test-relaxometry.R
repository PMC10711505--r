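te5 <- c(13.8, 70.4, 127.0, 183.6, 240.2)

test_that("both fitters recover noiseless decays exactly across the T2* range", {
  for (t2 in seq(20, 200, by = 20)) {
    sig <- 1000 * exp(-te5 / t2)
    ll <- fit_loglinear(sig, te5)
    nl <- fit_nlls(sig, te5)
    expect_equal(ll$t2star_ms, t2, tolerance = 1e-6)
    expect_equal(ll$s0, 1000, tolerance = 1e-6)
    expect_identical(ll$status, "ok")
    expect_equal(nl$t2star_ms, t2, tolerance = 1e-6)
    expect_equal(nl$s0, 1000, tolerance = 1e-6)
  }
})

test_that("degenerate decay curves get the documented statuses", {
  # constant signal: zero slope => clamped to t2_max
  cst <- fit_loglinear(rep(100, 5), te5)
  expect_identical(cst$status, "clamped_high")
  expect_equal(cst$t2star_ms, 500)
  # one zero sample is dropped, fit proceeds on the remaining 4 echoes
  sig <- 1000 * exp(-te5 / 66); sig[5] <- 0
  dr <- fit_loglinear(sig, te5)
  expect_identical(dr$status, "ok")
  expect_equal(dr$t2star_ms, 66, tolerance = 1e-6)
  # all zeros / too few positives => failed, no exception
  expect_identical(fit_loglinear(rep(0, 5), te5)$status, "failed")
  expect_identical(fit_nlls(rep(0, 5), te5)$status, "failed")
  expect_identical(fit_loglinear(c(100, 90, 0, 0, 0), te5)$status, "failed")
})

test_that("fitters are scale-equivariant and TE-unit consistent", {
  sig <- 850 * exp(-te5 / 45)
  for (fitter in list(fit_loglinear, fit_nlls)) {
    base <- fitter(sig, te5)
    scaled <- fitter(7.3 * sig, te5)
    expect_equal(scaled$s0, 7.3 * base$s0, tolerance = 1e-6)
    expect_equal(scaled$t2star_ms, base$t2star_ms, tolerance = 1e-8)
  }
  # seconds in => seconds out
  sec <- fit_loglinear(sig, te5 / 1000, t2_bounds = c(0.001, 0.5))
  expect_equal(sec$t2star_ms, 0.045, tolerance = 1e-6)
})

test_that("NLLS is less biased than log-linear under Rician noise", {
  t2 <- 66; s0 <- 100; snr <- 20
  n_rep <- 2000
  errs <- vapply(seq_len(n_rep), function(i) {
    sig <- rician_vec(s0 * exp(-te5 / t2), s0 / snr, seed = 1000 + i)
    c(abs(fit_loglinear(sig, te5)$t2star_ms - t2),
      abs(fit_nlls(sig, te5)$t2star_ms - t2))
  }, numeric(2))
  expect_lt(mean(errs[2, ]), mean(errs[1, ]))
})

test_that("whole-map fitting recovers truth, honours masks and propagates metadata", {
  ph <- make_phantom(30, grid_shape = c(32, 28, 24))
  img <- simulate_multiecho(ph, noise_model = "none")
  map <- fit_map(img, mask = ph$label_map > 0, method = "loglinear")
  inside <- ph$label_map != 0L
  expect_lt(max(abs(map$t2star[inside] - ph$truth_t2star[inside]) /
                  ph$truth_t2star[inside]), 1e-6)
  expect_lt(max(abs(map$s0[inside] - ph$truth_s0[inside]) /
                  ph$truth_s0[inside]), 1e-6)
  expect_identical(map$voxel_size, img$voxel_size)
  # outside the mask nothing is fitted
  expect_true(all(map$status[!inside] == 0L))
  # empty mask: all failed, no crash
  empty <- fit_map(img, mask = array(FALSE, dim(ph$label_map)))
  expect_true(all(empty$status == 0L))
  # grid mismatch rejected
  expect_error(fit_map(img, mask = array(TRUE, c(2, 2, 2))), "grids")
})

test_that("NLLS map never has larger residual sum-of-squares than log-linear", {
  ph <- make_phantom(28, grid_shape = c(32, 28, 24))
  img <- simulate_multiecho(ph, snr = 10, noise_model = "rician", seed = 6)
  lung <- ph$label_map >= 3L
  sel <- which(lung)[1:150]
  mask <- array(FALSE, dim(lung)); mask[sel] <- TRUE
  ll <- fit_map(img, mask, method = "loglinear")
  nl <- fit_map(img, mask, method = "nlls")
  flat <- matrix(img$data, ncol = length(img$echo_times))
  ssr <- function(m, v) sum((flat[v, ] - m$s0[v] * exp(-img$echo_times / m$t2star[v]))^2)
  for (v in sel[1:50]) expect_lte(ssr(nl, v), ssr(ll, v) + 1e-8)
})

test_that("quality masks follow status and r-squared thresholds", {
  ph <- make_phantom(30, grid_shape = c(32, 28, 24))
  img <- simulate_multiecho(ph, noise_model = "none")
  map <- fit_map(img, mask = ph$label_map > 0, method = "loglinear")
  qm0 <- quality_mask(map, r2_min = 0)
  expect_identical(array(qm0, dim(qm0)), array(map$status != 0L, dim(qm0)))
  # perfect noiseless fits: R^2 = 1 wherever signal decays
  qm99 <- quality_mask(map, r2_min = 0.99)
  expect_true(all(qm99[ph$label_map != 0L]))
  expect_false(any(quality_mask(map, r2_min = 1 + 1e-9)))
  expect_error(quality_mask(map, r2_min = -0.1), ">= 0")
  expect_error(quality_mask(map, statuses_allowed = "great"), "unknown")
})
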