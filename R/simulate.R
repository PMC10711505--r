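#' Multi-echo magnitude image container
#'
#' @param data 4-D array (x, y, z, echo) of non-negative magnitudes.
#' @param echo_times Echo times in ms, one per 4th-dimension volume,
#'   strictly increasing.
#' @param voxel_size Voxel dimensions (mm).
#' @param meta Optional list of extra metadata (TR, noise parameters, seed).
#' @return An object of class `multiecho_image`.
#' @export
multiecho_image <- function(data, echo_times, voxel_size, meta = list()) {
  if (length(dim(data)) != 4L)
    stop("data must be a 4-D (x, y, z, echo) array", call. = FALSE)
  if (dim(data)[4] != length(echo_times))
    stop(sprintf("echo count mismatch: %d volumes vs %d echo times",
                 dim(data)[4], length(echo_times)), call. = FALSE)
  if (length(echo_times) < 3L)
    stop("need at least 3 echoes", call. = FALSE)
  if (is.unsorted(echo_times, strictly = TRUE))
    stop("echo_times must be strictly increasing", call. = FALSE)
  if (any(data < 0)) stop("magnitude data must be >= 0", call. = FALSE)
  structure(list(data = data, echo_times = as.numeric(echo_times),
                 voxel_size = as.numeric(voxel_size), meta = meta),
            class = "multiecho_image")
}

#' @export
print.multiecho_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Multi-echo image %dx%dx%d, %d echoes (TE %s ms), voxel %s mm\n",
              d[1], d[2], d[3], d[4], paste(x$echo_times, collapse = "/"),
              paste(x$voxel_size, collapse = "x")))
  invisible(x)
}

#' Simulate a multi-echo acquisition of a phantom
#'
#' Generates magnitude images at each echo time from the phantom's ground
#' truth via the mono-exponential model S(TE) = S0 * exp(-TE / T2*), with
#' optional noise. Rician noise (the physical model for magnitude MRI) draws
#' the magnitude of the complex signal plus bivariate Gaussian noise;
#' `gaussian` adds real Gaussian noise and clips at zero; `none` returns the
#' noiseless decay. The noise level sigma is defined through
#' `snr = S0(lung) / sigma`, with S0(lung) the mean truth S0 over lung voxels
#' (mean over the whole body if the phantom has no lung voxels).
#'
#' @param phantom A [make_phantom()] result.
#' @param acquisition [acquisition_params()]; echo times to sample.
#' @param snr Signal-to-noise ratio; `Inf` disables noise.
#' @param noise_model One of "rician", "gaussian", "none".
#' @param seed Integer RNG seed for the noise draws.
#' @return A [multiecho_image()] whose metadata records TR, noise model,
#'   sigma, snr and seed.
#' @export
simulate_multiecho <- function(phantom, acquisition = acquisition_params(),
                               snr = Inf, noise_model = c("rician", "gaussian", "none"),
                               seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (noise_model != "none" && (!is.finite(snr) || snr <= 0) && !is.infinite(snr))
    stop("snr must be > 0 (or Inf / noise_model='none' for noiseless)", call. = FALSE)
  te <- acquisition$echo_times
  dims <- dim(phantom$label_map)
  s0 <- phantom$truth_s0
  t2 <- phantom$truth_t2star
  inv_t2 <- ifelse(is.na(t2), 0, 1 / t2)
  sig <- array(0, dim = c(dims, length(te)))
  for (e in seq_along(te)) sig[, , , e] <- s0 * exp(-te[e] * inv_t2)

  sigma <- 0
  if (noise_model != "none" && is.finite(snr)) {
    lung <- phantom$label_map %in% PHANTOM_LABELS[c("lung_right", "lung_left")]
    ref_s0 <- if (any(lung)) mean(phantom$truth_s0[lung])
              else mean(phantom$truth_s0[phantom$label_map != 0])
    sigma <- ref_s0 / snr
    sig <- with_seed(seed, apply_noise(sig, sigma, noise_model))
  }
  multiecho_image(sig, te, acquisition$voxel_size,
                  meta = list(repetition_time = acquisition$repetition_time,
                              flip_angle = acquisition$flip_angle,
                              noise_model = noise_model, sigma = sigma,
                              snr = snr, seed = seed,
                              ga_weeks = phantom$ga_weeks))
}

apply_noise <- function(sig, sigma, noise_model) {
  n <- length(sig)
  if (noise_model == "rician") {
    re <- sig + stats::rnorm(n, sd = sigma)
    im <- stats::rnorm(n, sd = sigma)
    array(sqrt(re^2 + im^2), dim = dim(sig))
  } else {
    array(pmax(sig + stats::rnorm(n, sd = sigma), 0), dim = dim(sig))
  }
}

#' Draw repeated Rician samples of one signal level
#'
#' Utility for noise-model checks: magnitudes of `n` independent Rician draws
#' around a true signal `s` with noise sigma. At high SNR the sample mean
#' exceeds `s` by approximately sigma^2 / (2 s) (the first-order Rician
#' bias).
#'
#' @param s True underlying signal.
#' @param sigma Gaussian noise SD per channel.
#' @param n Number of draws.
#' @param seed RNG seed.
#' @return Numeric vector of length `n`.
#' @export
rician_samples <- function(s, sigma, n, seed = 1L) {
  with_seed(seed, sqrt((s + stats::rnorm(n, sd = sigma))^2 +
                         stats::rnorm(n, sd = sigma)^2))
}
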