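test_that("published reference model carries the printed coefficients", {
  m <- published_model()
  expect_identical(m$mean_slope, 1.488884)
  expect_identical(m$mean_intercept, 21.997645)
  expect_identical(m$sd_slope, 1.488884)
  expect_identical(m$sd_intercept, -18.451005)
  expect_identical(m$ga_domain, c(20.6, 38.3))
  # SD positive at the domain floor: 1.488884 * 20.6 - 18.451005
  expect_gt(normative_sd(m, 20.6), 0)
  expect_equal(normative_sd(m, 20.6), 1.488884 * 20.6 - 18.451005)
})

test_that("z-scores and centiles follow the definitional identities", {
  m <- published_model()
  for (ga in c(21, 27.3, 30, 38)) {
    expect_equal(zscore(normative_mean(m, ga), ga, m)$z, 0)
    expect_equal(zscore(normative_mean(m, ga), ga, m)$centile, 50)
    expect_equal(zscore(normative_mean(m, ga) + normative_sd(m, ga), ga, m)$z, 1)
  }
  # ga = 30, observed = mean + 2 SD, via the printed formulas directly
  obs <- (1.488884 * 30 + 21.997645) + 2 * (1.488884 * 30 - 18.451005)
  expect_equal(zscore(obs, 30, m)$z, 2, tolerance = 1e-12)
  expect_error(zscore(60, 15, m), "domain")
  # round trip through arbitrary quantiles
  for (q in c(-2.5, -1, 0.3, 1.96)) {
    expect_equal(zscore(normative_mean(m, 25) + q * normative_sd(m, 25), 25, m)$z,
                 q, tolerance = 1e-12)
  }
})

test_that("reference bands are exact at the median, symmetric and round-trip", {
  m <- published_model()
  ga <- seq(21, 38, by = 1)
  b <- reference_band(m, ga, centiles = c(3, 10, 50, 90, 97))
  med <- b[b$centile == 50, ]
  expect_equal(med$value, normative_mean(m, med$ga_weeks))
  lo <- b[b$centile == 10, ]; hi <- b[b$centile == 90, ]
  expect_equal(lo$value + hi$value, 2 * normative_mean(m, lo$ga_weeks))
  # zscore(reference value at c) recovers centile c
  v97 <- b[b$centile == 97, ]
  expect_equal(zscore(v97$value, v97$ga_weeks, m)$centile,
               rep(97, nrow(v97)), tolerance = 1e-9)
  expect_error(reference_band(m, ga, centiles = c(0, 50)), "between")
  # monotone in centile at fixed GA
  at30 <- b[b$ga_weeks == 30, ]
  expect_true(all(diff(at30$value[order(at30$centile)]) > 0))
})

test_that("trend fitting: exact on noiseless lines, null slope covered, clustering", {
  ga <- seq(21, 38, length.out = 18)
  coh <- data.frame(subject_id = sprintf("S%02d", 1:18),
                    scan_id = sprintf("S%02d_1", 1:18),
                    ga_weeks = ga, t2star_ms = 1.488884 * ga + 21.997645)
  ft <- fit_trend(coh, "t2star_ms")
  expect_equal(ft$slope, 1.488884, tolerance = 1e-10)
  expect_equal(ft$intercept, 21.997645, tolerance = 1e-8)
  expect_equal(ft$r_squared, 1, tolerance = 1e-12)

  # metric independent of GA: slope CI covers 0
  set.seed(13)
  coh$t2star_ms <- rnorm(18, 60, 5)
  coh2 <- do.call(rbind, replicate(5, coh, simplify = FALSE))
  coh2$t2star_ms <- rnorm(90, 60, 5)
  ftn <- fit_trend(coh2, "t2star_ms")
  expect_true(abs(ftn$slope) < 1.96 * ftn$se_slope)

  # clustering changes only the SE/p, never the point estimates
  spec <- cohort_spec(n_subjects = 87)
  coh3 <- simulate_cohort(spec, seed = 21)
  plain <- fit_trend(coh3, "t2star_ms", cluster_by_subject = FALSE)
  clus <- fit_trend(coh3, "t2star_ms", cluster_by_subject = TRUE)
  expect_identical(plain$slope, clus$slope)
  expect_identical(plain$intercept, clus$intercept)
  expect_false(identical(plain$se_slope, clus$se_slope))

  expect_error(fit_trend(coh[1:2, ], "t2star_ms"), "at least 3")
  coh$ga_weeks <- 30
  expect_error(fit_trend(coh, "t2star_ms"), "singular|constant")
})

test_that("SD-trend estimators behave in the homoskedastic and zero-noise limits", {
  set.seed(19)
  n <- 4000
  ga <- runif(n, 21, 38)
  coh <- data.frame(subject_id = sprintf("S%04d", 1:n),
                    scan_id = sprintf("S%04d_1", 1:n),
                    ga_weeks = ga, t2star_ms = 60 + 1.5 * ga + rnorm(n, 0, 7))
  sf <- fit_sd_trend(coh, "t2star_ms")
  expect_equal(sf$sd_slope, 0, tolerance = 0.15)       # absolute: units ms/week
  expect_equal(sf$sd_intercept, 7, tolerance = 0.3 * 7)
  expect_false(sf$negative_sd_warning)

  coh$t2star_ms <- 60 + 1.5 * ga  # zero noise
  sf0 <- fit_sd_trend(coh, "t2star_ms")
  expect_equal(sf0$sd_slope, 0, tolerance = 1e-8)
  expect_equal(sf0$sd_intercept, 0, tolerance = 1e-7)
})

test_that("round-trip recovery of the published model is unbiased", {
  # single-replicate estimates carry sampling noise of a few percent on the
  # slopes and over 1 ms on the intercepts; averaging replicate simulations
  # isolates the bias, which should sit well within 10% of every coefficient
  m <- published_model()
  ga <- rep(21:38, each = 200)
  est <- vapply(1:15, function(r) {
    set.seed(700 + r)
    coh <- data.frame(subject_id = sprintf("S%04d", seq_along(ga)),
                      scan_id = sprintf("S%04d_1", seq_along(ga)),
                      ga_weeks = ga,
                      t2star_ms = rnorm(length(ga), normative_mean(m, ga),
                                        normative_sd(m, ga)))
    mf <- fit_trend(coh, "t2star_ms")
    sf <- fit_sd_trend(coh, "t2star_ms", method = "binned")
    c(mf$slope, mf$intercept, sf$sd_slope, sf$sd_intercept)
  }, numeric(4))
  avg <- rowMeans(est)
  expect_equal(avg[1], m$mean_slope, tolerance = 0.1)
  expect_equal(avg[2], m$mean_intercept, tolerance = 0.1)
  expect_equal(avg[3], m$sd_slope, tolerance = 0.1)
  expect_equal(avg[4], m$sd_intercept, tolerance = 0.1)
})

test_that("slope confidence intervals achieve near-nominal coverage", {
  m <- published_model()
  covered <- 0L
  n_rep <- 500L
  spec <- cohort_spec(n_subjects = 87)
  for (i in seq_len(n_rep)) {
    coh <- simulate_cohort(spec, seed = 3000 + i)
    ft <- fit_trend(coh, "t2star_ms", cluster_by_subject = TRUE)
    if (abs(ft$slope - m$mean_slope) <= 1.96 * ft$se_slope)
      covered <- covered + 1L
  }
  expect_gte(covered / n_rep, 0.9)
})
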