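#' Lung label mask
#'
#' Integer label volume with the fixed convention 0 = background,
#' 1 = right lung, 2 = left lung.
#'
#' @param labels Integer volume with values in \{0, 1, 2\}.
#' @param voxel_size Voxel dimensions (mm).
#' @return An object of class `lung_mask`.
#' @export
lung_mask <- function(labels, voxel_size) {
  u <- unique(as.vector(labels))
  bad <- setdiff(u, c(0L, 1L, 2L))
  if (length(bad))
    stop("unknown mask labels: ", paste(sort(bad), collapse = ", "),
         " (expected 0=background, 1=right, 2=left)", call. = FALSE)
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size)),
            class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf("Lung mask %s: %d right, %d left voxels\n",
              paste(dim(x$labels), collapse = "x"),
              sum(x$labels == 1L), sum(x$labels == 2L)))
  invisible(x)
}

roi_labels <- function(roi = c("right", "left", "both")) {
  roi <- match.arg(roi)
  switch(roi, right = 1L, left = 2L, both = c(1L, 2L))
}

#' Per-lung T2* summary statistics
#'
#' Mean, SD and median T2* plus voxel count and volume over an ROI of the
#' lung mask, optionally intersected with a fit-quality mask. The "both"
#' ROI pools right- and left-lung voxels (so its mean is the voxel-count
#' weighted mean of the per-lung means, not their average). Volume depends
#' only on the mask and voxel size: `volume_ml = n_voxels * voxel volume /
#' 1000`. An empty ROI yields `n_voxels = 0` with NA statistics and
#' `undefined = TRUE`, never an error, so cohort batch runs always
#' complete.
#'
#' @param map A [fit_map()] result.
#' @param mask A [lung_mask()] on the same grid.
#' @param roi One of "right", "left", "both".
#' @param quality Optional logical volume (e.g. [quality_mask()]) further
#'   restricting the voxels.
#' @return A one-row data frame: `roi`, `n_voxels`, `mean_t2star`,
#'   `sd_t2star`, `median_t2star`, `volume_ml`, `undefined`.
#' @export
summarize_roi <- function(map, mask, roi = c("right", "left", "both"),
                          quality = NULL) {
  roi <- match.arg(roi)
  stopifnot_same_grid(dim(map$t2star), dim(mask$labels), "map and mask")
  sel <- mask$labels %in% roi_labels(roi)
  if (!is.null(quality)) {
    stopifnot_same_grid(dim(quality), dim(mask$labels), "quality mask and mask")
    sel <- sel & as.logical(quality)
  }
  n <- sum(sel)
  vals <- map$t2star[sel]
  vals <- vals[is.finite(vals)]
  vol_ml <- n * prod(mask$voxel_size) / 1000
  if (length(vals) == 0L)
    return(data.frame(roi = roi, n_voxels = n, mean_t2star = NA_real_,
                      sd_t2star = NA_real_, median_t2star = NA_real_,
                      volume_ml = vol_ml, undefined = TRUE))
  data.frame(roi = roi, n_voxels = n,
             mean_t2star = mean(vals),
             sd_t2star = if (length(vals) > 1) stats::sd(vals) else 0,
             median_t2star = stats::median(vals),
             volume_ml = vol_ml, undefined = FALSE)
}

#' ROI histogram of T2* voxel values
#'
#' @param map A [fit_map()] result.
#' @param mask A [lung_mask()] on the same grid.
#' @param roi One of "right", "left", "both".
#' @param bins Number of bins (>= 1) or an explicit vector of strictly
#'   increasing bin edges (ms).
#' @return A list of class `roi_histogram`: `bin_edges`, `counts`, `roi`,
#'   `n_voxels`. Counts sum to the number of finite ROI voxel values.
#' @export
roi_histogram <- function(map, mask, roi = c("right", "left", "both"),
                          bins = 30) {
  roi <- match.arg(roi)
  stopifnot_same_grid(dim(map$t2star), dim(mask$labels), "map and mask")
  vals <- map$t2star[mask$labels %in% roi_labels(roi)]
  vals <- vals[is.finite(vals)]
  if (length(bins) == 1L) {
    if (bins < 1) stop("bins must be >= 1", call. = FALSE)
    rng <- if (length(vals)) range(vals) else map$t2_bounds
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = bins + 1)
  } else {
    edges <- as.numeric(bins)
    if (is.unsorted(edges, strictly = TRUE))
      stop("bin edges must be strictly increasing", call. = FALSE)
  }
  counts <- if (length(vals))
    as.integer(table(cut(vals, edges, include.lowest = TRUE)))
  else integer(length(edges) - 1L)
  structure(list(bin_edges = edges, counts = counts, roi = roi,
                 n_voxels = length(vals)),
            class = "roi_histogram")
}

#' Paired right-left lung comparison
#'
#' Two-sided paired t-test of right minus left differences of a per-lung
#' metric across scans. Columns `<metric>_right` and `<metric>_left` are
#' paired by `scan_id`. When every difference is identical (zero variance)
#' the t statistic is undefined; the result is flagged `degenerate`, with
#' p = 1 when the common difference is 0 and p reported below machine
#' precision otherwise.
#'
#' @param cohort Cohort data frame containing `scan_id` and both per-lung
#'   metric columns.
#' @param metric Base metric name, e.g. "t2star_ms" or "volume_ml".
#' @return List: `mean_diff` (right - left), `statistic`, `p_value`,
#'   `n_pairs`, `degenerate`.
#' @export
compare_lungs <- function(cohort, metric) {
  rc <- paste0(metric, "_right"); lc <- paste0(metric, "_left")
  if (!all(c(rc, lc) %in% names(cohort)))
    stop(sprintf("need columns '%s' and '%s'", rc, lc), call. = FALSE)
  d <- cohort[[rc]] - cohort[[lc]]
  d <- d[is.finite(d)]
  if (length(d) < 2L) stop("need >= 2 complete right/left pairs", call. = FALSE)
  if (stats::sd(d) == 0) {
    md <- mean(d)
    return(list(mean_diff = md,
                statistic = if (md == 0) 0 else sign(md) * Inf,
                p_value = if (md == 0) 1 else .Machine$double.xmin,
                n_pairs = length(d), degenerate = TRUE))
  }
  tt <- stats::t.test(d)
  list(mean_diff = unname(tt$estimate), statistic = unname(tt$statistic),
       p_value = tt$p.value, n_pairs = length(d), degenerate = FALSE)
}
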