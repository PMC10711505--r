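test_that("worked toy examples match hand enumeration", {
  # 2x2 slab with unit diagonal, box size 1: masses {1,0,0,1} => 0.5/0.25 = 2
  slab <- matrix(c(1, 0, 0, 1), 2, 2)
  gb <- gliding_box(slab, matrix(TRUE, 2, 2), 1)
  expect_equal(gb$lambda, 2)
  expect_identical(gb$n_boxes, 4L)
  # 4x4 checkerboard, box size 2: every 2x2 box holds mass 2 => lambda 1
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  gb2 <- gliding_box(cb, matrix(TRUE, 4, 4), 2)
  expect_equal(gb2$lambda, 1)
  expect_identical(gb2$n_boxes, 9L)
  # constant positive field on a full mask: lambda exactly 1 at any size
  cst <- array(5, c(6, 6, 6))
  for (r in c(1, 2, 3, 5))
    expect_equal(gliding_box(cst, array(TRUE, c(6, 6, 6)), r)$lambda, 1)
})

test_that("implementation equals exhaustive enumeration on random small volumes", {
  set.seed(17)
  for (rep in 1:12) {
    d <- sample(4:8, 3, replace = TRUE)
    vals <- array(runif(prod(d), 0, 10), d)
    mask <- array(runif(prod(d)) < 0.8, d)
    if (!any(mask)) next
    for (r in 1:3) {
      idx <- which(mask, arr.ind = TRUE)
      bb <- apply(idx, 2, max) - apply(idx, 2, min) + 1L
      if (r > min(bb)) next
      got <- gliding_box(vals, mask, r)
      want <- brute_lacunarity(vals, mask, r)
      if (is.na(want)) expect_true(is.na(got$lambda))
      else expect_equal(got$lambda, want, tolerance = 1e-12)
    }
  }
})

test_that("lacunarity invariants: lower bound, intensity scale, translation", {
  set.seed(23)
  vals <- array(runif(6^3, 0, 4), c(6, 6, 6))
  mask <- array(TRUE, c(6, 6, 6))
  for (r in c(2, 3)) {
    lam <- gliding_box(vals, mask, r)$lambda
    expect_gte(lam, 1)
    expect_equal(gliding_box(3.7 * vals, mask, r)$lambda, lam, tolerance = 1e-12)
  }
  # translate map and mask together inside a larger volume
  big_v <- array(0, c(10, 10, 10)); big_m <- array(FALSE, c(10, 10, 10))
  big_v[1:6, 1:6, 1:6] <- vals; big_m[1:6, 1:6, 1:6] <- TRUE
  sh_v <- array(0, c(10, 10, 10)); sh_m <- array(FALSE, c(10, 10, 10))
  sh_v[4:9, 3:8, 5:10] <- vals; sh_m[4:9, 3:8, 5:10] <- TRUE
  expect_equal(gliding_box(big_v, big_m, 2)$lambda,
               gliding_box(sh_v, sh_m, 2)$lambda, tolerance = 1e-12)
})

test_that("curves flag infeasible sizes and order textures sensibly", {
  dims <- c(12, 12, 10)
  labels <- array(0L, dims); labels[3:10, 3:10, 3:8] <- 1L
  mask <- lung_mask(labels, c(3, 3, 3))
  cst_map <- fake_map(array(66, dims))
  set.seed(41)
  noise_map <- fake_map(array(runif(prod(dims), 10, 120), dims))

  cv_cst <- lacunarity_curve(cst_map, mask, "right", box_sizes = c(2, 3, 4))
  expect_true(all(abs(cv_cst$lambda - 1) < 0.02))
  cv_noise <- lacunarity_curve(noise_map, mask, "right", box_sizes = c(2, 3, 4))
  expect_true(all(cv_noise$lambda > cv_cst$lambda))

  # a size beyond the ROI bounding box is flagged, not dropped
  cv <- lacunarity_curve(cst_map, mask, "right", box_sizes = c(2, 30))
  expect_identical(nrow(cv), 2L)
  expect_false(is.na(cv$flag[cv$box_size == 30]))
  expect_error(lacunarity_curve(cst_map, mask, "right", box_sizes = c(30, 40)),
               "flagged")
})

test_that("scores aggregate curves as documented", {
  dims <- c(10, 10, 8)
  labels <- array(0L, dims); labels[2:9, 2:9, 2:7] <- 1L
  mask <- lung_mask(labels, c(3, 3, 3))
  set.seed(5)
  map <- fake_map(array(runif(prod(dims), 20, 100), dims))
  cv <- lacunarity_curve(map, mask, "right", box_sizes = c(2, 3, 4))
  sc <- lacunarity_score(cv, "mean_log")
  expect_equal(sc$value, mean(log(cv$lambda)))
  at3 <- lacunarity_score(cv, "at_fixed_box", box_size = 3)
  expect_equal(at3$value, cv$lambda[cv$box_size == 3])
  # curve identically 1 => mean_log score 0
  cv1 <- lacunarity_curve(fake_map(array(66, dims)), mask, "right",
                          box_sizes = c(2))
  expect_equal(lacunarity_score(cv1, "mean_log")$value, 0, tolerance = 1e-4)
})

test_that("lacunarity score rises with GA when texture heterogeneity grows", {
  gas <- seq(22, 38, by = 2)
  scores <- vapply(seq_along(gas), function(i) {
    g <- gas[i]
    het <- 0.02 + 0.01 * (g - 20)  # heterogeneity increasing with GA
    ph <- make_phantom(g, grid_shape = c(32, 28, 24),
                       tissues = default_tissues(g, lung_heterogeneity_sd = het),
                       seed = 100 + i)
    img <- simulate_multiecho(ph, noise_model = "none")
    map <- fit_map(img, mask = ph$label_map >= 3L, method = "loglinear")
    cv <- lacunarity_curve(map, phantom_lung_mask(ph), "both",
                           box_sizes = c(2, 3))
    lacunarity_score(cv)$value
  }, numeric(1))
  ft <- stats::lm(scores ~ gas)
  expect_gt(coef(ft)[2], 0)
  expect_lt(summary(ft)$coefficients[2, 4], 0.05)
})
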