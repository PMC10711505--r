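#' Multi-echo acquisition parameters
#'
#' Bundle of sequence parameters used by the simulator and carried as image
#' metadata. Defaults correspond to a multi-echo gradient-echo single-shot EPI
#' protocol at 3 T with 3 mm isotropic voxels and five echoes.
#'
#' @param echo_times Numeric vector of echo times in ms, strictly increasing,
#'   all positive. Default `c(13.8, 70.4, 127.0, 183.6, 240.2)`.
#' @param repetition_time Repetition time in ms. Default 3000.
#' @param flip_angle Flip angle in degrees. Metadata only; its effect on the
#'   signal is folded into S0. Default 90.
#' @param voxel_size Numeric length-3 voxel dimensions (dx, dy, dz) in mm,
#'   all positive. Default `c(3, 3, 3)`.
#' @return An object of class `acquisition_params`.
#' @examples
#' acq <- acquisition_params()
#' acq$echo_times
#' @export
acquisition_params <- function(echo_times = c(13.8, 70.4, 127.0, 183.6, 240.2),
                               repetition_time = 3000,
                               flip_angle = 90,
                               voxel_size = c(3, 3, 3)) {
  echo_times <- as.numeric(echo_times)
  if (length(echo_times) < 1L || any(!is.finite(echo_times)) || any(echo_times <= 0))
    stop("echo_times must be finite and positive", call. = FALSE)
  if (is.unsorted(echo_times, strictly = TRUE))
    stop("echo_times must be strictly increasing", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be three positive numbers (mm)", call. = FALSE)
  structure(list(echo_times = echo_times,
                 repetition_time = as.numeric(repetition_time),
                 flip_angle = as.numeric(flip_angle),
                 voxel_size = voxel_size),
            class = "acquisition_params")
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat("Multi-echo acquisition:\n")
  cat("  TEs (ms):  ", paste(x$echo_times, collapse = ", "), "\n")
  cat("  TR (ms):   ", x$repetition_time, "\n")
  cat("  flip (deg):", x$flip_angle, "\n")
  cat("  voxel (mm):", paste(x$voxel_size, collapse = " x "), "\n")
  invisible(x)
}

#' Tissue signal parameters
#'
#' Per-tissue parameters of the mono-exponential signal model
#' S(TE) = S0 * exp(-TE / T2*). `heterogeneity_sd` is the fractional standard
#' deviation of a multiplicative spatial texture applied to the tissue's T2*
#' when a phantom is built, emulating within-tissue heterogeneity.
#'
#' @param label Integer tissue label (matches the phantom label map).
#' @param name Human-readable tissue name.
#' @param s0 Equilibrium signal, arbitrary units, > 0.
#' @param t2star_ms T2* in ms, > 0.
#' @param heterogeneity_sd Fractional SD (>= 0) of the multiplicative T2*
#'   texture; 0 means a perfectly homogeneous tissue.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(label, name, s0, t2star_ms, heterogeneity_sd = 0) {
  if (!is.finite(s0) || s0 <= 0) stop("s0 must be > 0", call. = FALSE)
  if (!is.finite(t2star_ms) || t2star_ms <= 0) stop("t2star_ms must be > 0", call. = FALSE)
  if (!is.finite(heterogeneity_sd) || heterogeneity_sd < 0)
    stop("heterogeneity_sd must be >= 0", call. = FALSE)
  structure(list(label = as.integer(label), name = as.character(name),
                 s0 = as.numeric(s0), t2star_ms = as.numeric(t2star_ms),
                 heterogeneity_sd = as.numeric(heterogeneity_sd)),
            class = "tissue_params")
}

# Phantom label conventions, shared across the package.
PHANTOM_LABELS <- c(background = 0L, body = 1L, heart = 2L,
                    lung_right = 3L, lung_left = 4L)

#' Default phantom tissue set for a given gestational age
#'
#' Lung T2* is placed on the published normative mean curve at `ga_weeks`, so
#' that an end-to-end phantom run lands on the reference model by
#' construction. Other tissues use fixed representative values at 3 T.
#'
#' @param ga_weeks Gestational age in weeks.
#' @param lung_heterogeneity_sd Fractional SD of the lung T2* texture field.
#' @return A list of [tissue_params()] objects keyed by tissue name.
#' @export
default_tissues <- function(ga_weeks, lung_heterogeneity_sd = 0) {
  lung_t2 <- normative_mean(published_model(), ga_weeks, check_domain = FALSE)
  list(
    body       = tissue_params(PHANTOM_LABELS[["body"]], "body", s0 = 800, t2star_ms = 35),
    heart      = tissue_params(PHANTOM_LABELS[["heart"]], "heart", s0 = 900, t2star_ms = 45),
    lung_right = tissue_params(PHANTOM_LABELS[["lung_right"]], "lung_right",
                               s0 = 1000, t2star_ms = lung_t2,
                               heterogeneity_sd = lung_heterogeneity_sd),
    lung_left  = tissue_params(PHANTOM_LABELS[["lung_left"]], "lung_left",
                               s0 = 1000, t2star_ms = lung_t2,
                               heterogeneity_sd = lung_heterogeneity_sd)
  )
}
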