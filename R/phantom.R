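#' Digital fetal thorax phantom
#'
#' Builds a simple geometric thorax on a regular voxel grid: a cylindrical
#' body along the head-foot axis containing a spherical heart and two lung
#' ellipsoids. Total analytic lung volume grows linearly with gestational age
#' and the left lung's analytic volume is fixed at 0.85 times the right
#' lung's, reflecting the smaller left lung. The geometry is deliberately
#' minimal so that every derived quantity (volume, mean T2*) has a
#' closed-form ground truth.
#'
#' Ground-truth S0 and T2* maps are painted from the tissue table; a tissue
#' with `heterogeneity_sd > 0` receives a multiplicative log-normal texture
#' with unit mean and fractional SD equal to `heterogeneity_sd` (voxelwise
#' independent draws).
#'
#' @param ga_weeks Gestational age in weeks, in \[18, 40\].
#' @param grid_shape Integer length-3 grid dimensions. Default c(48, 48, 40).
#' @param acquisition [acquisition_params()]; supplies the voxel size.
#' @param tissues List of [tissue_params()] as from [default_tissues()];
#'   must contain body, heart, lung_right and lung_left entries.
#' @param seed Integer seed for the texture field (ignored when no tissue has
#'   heterogeneity).
#' @return An object of class `phantom`: label map, truth_s0, truth_t2star
#'   volumes, voxel_size, ga_weeks, and `analytic_volumes_ml` (right, left,
#'   total lung, in mL) of the generating ellipsoids.
#' @examples
#' ph <- make_phantom(30)
#' ph$analytic_volumes_ml
#' @export
make_phantom <- function(ga_weeks,
                         grid_shape = c(48, 48, 40),
                         acquisition = acquisition_params(),
                         tissues = default_tissues(ga_weeks),
                         seed = 1L) {
  if (!is.finite(ga_weeks) || ga_weeks < 18 || ga_weeks > 40)
    stop("ga_weeks must lie in [18, 40]", call. = FALSE)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop("grid_shape must be three integers >= 4", call. = FALSE)
  need <- c("body", "heart", "lung_right", "lung_left")
  if (!all(need %in% names(tissues)))
    stop("tissues must contain: ", paste(need, collapse = ", "), call. = FALSE)

  vox <- acquisition$voxel_size
  geom <- phantom_geometry(ga_weeks)
  fov <- grid_shape * vox

  # lungs must fit inside the grid with a 1-voxel margin
  ext <- lung_extents_mm(geom)
  if (any(ext + 2 * vox > fov))
    stop(sprintf(paste0("grid too small for GA %.1f weeks: lungs need ",
                        "%.0fx%.0fx%.0f mm plus margin, field of view is ",
                        "%.0fx%.0fx%.0f mm"),
                 ga_weeks, ext[1], ext[2], ext[3], fov[1], fov[2], fov[3]),
         call. = FALSE)

  # voxel-centre world coordinates, origin at the grid centre
  cx <- (seq_len(grid_shape[1]) - 0.5) * vox[1] - fov[1] / 2
  cy <- (seq_len(grid_shape[2]) - 0.5) * vox[2] - fov[2] / 2
  cz <- (seq_len(grid_shape[3]) - 0.5) * vox[3] - fov[3] / 2
  X <- array(cx, dim = grid_shape)
  Y <- array(rep(cy, each = grid_shape[1]), dim = grid_shape)
  Z <- array(rep(cz, each = grid_shape[1] * grid_shape[2]), dim = grid_shape)

  labels <- array(PHANTOM_LABELS[["background"]], dim = grid_shape)
  # body: cylinder along z spanning the lung extent plus margin
  half_h <- ext[3] / 2 + 2 * vox[3]
  in_body <- (X^2 + Y^2 <= geom$body_radius^2) & (abs(Z) <= half_h)
  labels[in_body] <- PHANTOM_LABELS[["body"]]
  # heart: sphere at midline, slightly anterior
  hc <- geom$heart_centre
  in_heart <- ((X - hc[1])^2 + (Y - hc[2])^2 + (Z - hc[3])^2) <= geom$heart_radius^2
  labels[in_heart] <- PHANTOM_LABELS[["heart"]]
  # lungs: ellipsoids left/right of midline (override heart on overlap)
  for (side in c("right", "left")) {
    ctr <- geom[[paste0(side, "_centre")]]
    ax <- geom[[paste0(side, "_semiaxes")]]
    inside <- ((X - ctr[1]) / ax[1])^2 + ((Y - ctr[2]) / ax[2])^2 +
      ((Z - ctr[3]) / ax[3])^2 <= 1
    labels[inside] <- PHANTOM_LABELS[[paste0("lung_", side)]]
  }

  truth_s0 <- array(0, dim = grid_shape)
  truth_t2 <- array(NA_real_, dim = grid_shape)
  known <- PHANTOM_LABELS[["background"]]
  for (tp in tissues) {
    sel <- labels == tp$label
    known <- c(known, tp$label)
    if (!any(sel)) next
    truth_s0[sel] <- tp$s0
    t2 <- rep(tp$t2star_ms, sum(sel))
    if (tp$heterogeneity_sd > 0) {
      sdl <- sqrt(log1p(tp$heterogeneity_sd^2))
      t2 <- with_seed(derive_seed(seed, tp$label),
                      t2 * stats::rlnorm(length(t2), meanlog = -sdl^2 / 2, sdlog = sdl))
    }
    truth_t2[sel] <- t2
  }
  if (!all(unique(as.vector(labels)) %in% known))
    stop("label map contains tissues with no parameters", call. = FALSE)

  vol_right <- ellipsoid_volume_ml(geom$right_semiaxes)
  structure(list(label_map = labels,
                 truth_s0 = truth_s0,
                 truth_t2star = truth_t2,
                 voxel_size = vox,
                 ga_weeks = ga_weeks,
                 tissues = tissues,
                 analytic_volumes_ml = c(right = vol_right,
                                         left = 0.85 * vol_right,
                                         total = 1.85 * vol_right)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Thorax phantom, GA %.1f weeks, grid %s, voxel %s mm\n",
              x$ga_weeks, paste(dim(x$label_map), collapse = "x"),
              paste(x$voxel_size, collapse = "x")))
  v <- x$analytic_volumes_ml
  cat(sprintf("  analytic lung volumes (mL): right %.1f, left %.1f, total %.1f\n",
              v["right"], v["left"], v["total"]))
  invisible(x)
}

# Total lung volume model: linear growth in GA, 3 mL/week from a 15-week
# zero-intercept; keeps >= 500 lung voxels at 3 mm resolution from GA 21.
total_lung_volume_ml <- function(ga_weeks) 3.0 * (ga_weeks - 15)

# Analytic geometry (all mm) for a given GA. Ellipsoid axis ratios are fixed;
# only the scale grows, so volume ordering is exact at every GA.
phantom_geometry <- function(ga_weeks) {
  v_total <- total_lung_volume_ml(ga_weeks) * 1000  # mm^3
  v_right <- v_total / 1.85
  ratios <- c(0.65, 0.55, 1.0)                      # LR, AP, SI axis ratios
  s_right <- (3 * v_right / (4 * pi * prod(ratios)))^(1 / 3)
  s_left <- s_right * 0.85^(1 / 3)
  ax_r <- ratios * s_right
  ax_l <- ratios * s_left
  offset <- ax_r[1] + 6                             # lateral lung offset from midline
  list(right_semiaxes = ax_r, left_semiaxes = ax_l,
       right_centre = c(offset, 0, 0), left_centre = c(-offset, 0, 0),
       heart_radius = 0.45 * s_right, heart_centre = c(0, 6, -0.2 * s_right),
       body_radius = offset + ax_r[1] + 6)
}

lung_extents_mm <- function(geom) {
  x_ext <- 2 * (abs(geom$right_centre[1]) + geom$right_semiaxes[1])
  y_ext <- 2 * max(geom$right_semiaxes[2], geom$left_semiaxes[2])
  z_ext <- 2 * max(geom$right_semiaxes[3], geom$left_semiaxes[3])
  c(x_ext, y_ext, z_ext)
}

ellipsoid_volume_ml <- function(semiaxes) 4 / 3 * pi * prod(semiaxes) / 1000

#' Lung label mask from a phantom
#'
#' Converts a phantom's 5-tissue label map to the 3-label lung mask
#' convention used throughout the package: 0 = background, 1 = right lung,
#' 2 = left lung.
#'
#' @param phantom A [make_phantom()] result.
#' @return A `lung_mask` object (see [lung_mask()]).
#' @export
phantom_lung_mask <- function(phantom) {
  lab <- array(0L, dim = dim(phantom$label_map))
  lab[phantom$label_map == PHANTOM_LABELS[["lung_right"]]] <- 1L
  lab[phantom$label_map == PHANTOM_LABELS[["lung_left"]]] <- 2L
  lung_mask(lab, phantom$voxel_size)
}
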