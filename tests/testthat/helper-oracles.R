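# Independent oracles and small fixture builders used across the suite.

# Exhaustive gliding-box lacunarity: enumerate every box position directly.
# Same definition as the implementation but with none of its integral-image
# machinery; O(positions * box volume).
brute_lacunarity <- function(vals, mask, r, min_coverage = 0.9) {
  d <- dim(mask); nd <- length(d)
  idx <- which(mask, arr.ind = TRUE)
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 1)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  starts <- do.call(expand.grid, lapply(seq_len(nd), function(k) lo[k]:(hi[k] - r + 1)))
  masses <- numeric(0)
  for (i in seq_len(nrow(starts))) {
    rng <- lapply(seq_len(nd), function(k) starts[i, k]:(starts[i, k] + r - 1))
    m_box <- do.call(`[`, c(list(mask), rng, list(drop = FALSE)))
    if (sum(m_box) < min_coverage * r^nd - 1e-9) next
    v_box <- do.call(`[`, c(list(vals), rng, list(drop = FALSE)))
    masses <- c(masses, sum(v_box[m_box]))
  }
  if (!length(masses) || mean(masses) == 0) return(NA_real_)
  mean(masses^2) / mean(masses)^2
}

# Two-way ANOVA mean squares via stats::aov (independent of the closed-form
# sums used by icc_a1), plus the absolute-agreement single-measures ICC
# assembled from them.
aov_icc_a1 <- function(X) {
  n <- nrow(X); k <- ncol(X)
  df <- data.frame(y = as.vector(X),
                   target = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ target + rater, data = df))[[1]]
  msr <- tab["target", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Evaluate an expression under a fixed seed without touching global state.
with_fixed_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# One Rician draw per element of a signal vector.
rician_vec <- function(s, sigma, seed) {
  set.seed(seed)
  sqrt((s + rnorm(length(s), 0, sigma))^2 + rnorm(length(s), 0, sigma)^2)
}

# Tiny multi-echo image with known decay at every voxel.
toy_image <- function(dims = c(4, 4, 3), s0 = 1000, t2 = 66,
                      te = c(13.8, 70.4, 127.0, 183.6, 240.2)) {
  data <- array(0, dim = c(dims, length(te)))
  for (e in seq_along(te)) data[, , , e] <- s0 * exp(-te[e] / t2)
  multiecho_image(data, te, c(3, 3, 3))
}

# A t2star_map-like object with given t2star values (for ROI/lacunarity
# tests that do not need a real fit).
fake_map <- function(t2star, voxel_size = c(3, 3, 3)) {
  ok <- array(ifelse(is.finite(t2star), 1L, 0L), dim = dim(t2star))
  structure(list(t2star = t2star,
                 s0 = array(1000, dim = dim(t2star)),
                 r_squared = array(1, dim = dim(t2star)),
                 status = ok, voxel_size = voxel_size,
                 method = "loglinear", t2_bounds = c(1, 500)),
            class = "t2star_map")
}
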