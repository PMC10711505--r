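#' @name lacunarity
#' @title Gliding-box lacunarity of masked intensity maps
#' @description
#' Lacunarity quantifies the "gappiness"/heterogeneity of a texture. The
#' gliding-box variant used here slides a cubic box of edge `box_size`
#' (square in 2-D) by unit steps over the mask bounding box; a box is
#' retained when at least 90% of its voxels fall inside the mask, its mass M
#' is the sum of map values over the in-mask voxels it covers, and
#' Lambda = mean(M^2) / mean(M)^2 over retained boxes. Lambda is 1 for a
#' homogeneous field, larger for heterogeneous ones, and is invariant to
#' multiplying the map by a positive constant. Boxes operate on intensities
#' directly (continuous-mass lacunarity), not on a binarised field, which
#' suits quantitative T2* maps.
NULL

# Sliding-window sum of length r along dimension `along` (any-dimensional).
window_sum <- function(a, r, along) {
  d <- dim(a)
  perm <- c(along, setdiff(seq_along(d), along))
  m <- aperm(a, perm)
  dm <- dim(m)
  mm <- matrix(m, nrow = dm[1])
  cs <- rbind(0, apply(mm, 2, cumsum))
  out <- cs[(r + 1):(dm[1] + 1), , drop = FALSE] - cs[1:(dm[1] - r + 1), , drop = FALSE]
  dim(out) <- c(dm[1] - r + 1L, dm[-1])
  aperm(out, order(perm))
}

# Sums over every r^d box at unit step (integral-image decomposition).
box_sums <- function(a, r) {
  for (k in seq_along(dim(a))) a <- window_sum(a, r, k)
  a
}

#' Gliding-box lacunarity at one box size
#'
#' @param map_values Numeric array (2-D or 3-D) of intensities; values
#'   outside the mask are ignored.
#' @param mask Logical (or 0/1) array of the same shape.
#' @param box_size Box edge length in voxels; must be >= 1 and no larger
#'   than the smallest dimension of the mask bounding box.
#' @param min_coverage Minimum in-mask fraction for a box to be retained
#'   (default 0.9).
#' @return List: `lambda` (NA with `flag` set when no box is retained or all
#'   masses are zero), `n_boxes`, `flag` (NA_character_ when clean).
#' @examples
#' slab <- matrix(c(1, 0, 0, 1), 2, 2)
#' gliding_box(slab, matrix(TRUE, 2, 2), 1)$lambda  # 2
#' @export
gliding_box <- function(map_values, mask, box_size, min_coverage = 0.9) {
  mask <- array(as.logical(mask), dim = dim(mask))
  stopifnot_same_grid(dim(map_values), dim(mask), "map and mask")
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  nd <- length(dim(mask))
  idx <- which(mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  bb <- hi - lo + 1L
  if (box_size < 1 || box_size > min(bb))
    stop(sprintf("box_size %d outside [1, %d] (smallest bounding-box dim)",
                 box_size, min(bb)), call. = FALSE)
  # crop to bounding box
  args <- lapply(seq_len(nd), function(k) lo[k]:hi[k])
  msk <- do.call(`[`, c(list(mask), args, list(drop = FALSE)))
  vals <- do.call(`[`, c(list(map_values), args, list(drop = FALSE)))
  vals[!msk | !is.finite(vals)] <- 0
  counts <- box_sums(array(as.numeric(msk), dim = dim(msk)), box_size)
  masses <- box_sums(vals, box_size)
  keep <- counts >= min_coverage * box_size^nd - 1e-9
  if (!any(keep))
    return(list(lambda = NA_real_, n_boxes = 0L, flag = "no_retained_boxes"))
  m <- masses[keep]
  if (mean(m) == 0)
    return(list(lambda = NA_real_, n_boxes = sum(keep), flag = "zero_mean_mass"))
  list(lambda = mean(m^2) / mean(m)^2, n_boxes = sum(keep),
       flag = NA_character_)
}

#' Lacunarity curve over box sizes
#'
#' Evaluates [gliding_box()] on the T2* values of an ROI at each requested
#' box size. Sizes that cannot be evaluated (too large for the ROI, no
#' retained boxes, zero mass) are flagged in the output, never dropped
#' silently.
#'
#' @param map A [fit_map()] result.
#' @param mask A [lung_mask()] on the same grid.
#' @param roi One of "right", "left", "both".
#' @param box_sizes Integer vector of box edges, strictly increasing.
#'   Default c(2, 3, 4, 6, 8), spanning sub-lobe scales at 3 mm resolution.
#' @return A data frame of class `lacunarity_curve` with columns `box_size`,
#'   `lambda`, `n_boxes`, `flag`, and attribute `roi`.
#' @export
lacunarity_curve <- function(map, mask, roi = c("right", "left", "both"),
                             box_sizes = c(2, 3, 4, 6, 8)) {
  roi <- match.arg(roi)
  if (is.unsorted(box_sizes, strictly = TRUE))
    stop("box_sizes must be strictly increasing", call. = FALSE)
  stopifnot_same_grid(dim(map$t2star), dim(mask$labels), "map and mask")
  sel <- array(mask$labels %in% roi_labels(roi), dim = dim(mask$labels))
  rows <- lapply(box_sizes, function(r) {
    gb <- tryCatch(gliding_box(map$t2star, sel, r),
                   error = function(e) list(lambda = NA_real_, n_boxes = 0L,
                                            flag = conditionMessage(e)))
    data.frame(box_size = r, lambda = gb$lambda, n_boxes = gb$n_boxes,
               flag = gb$flag)
  })
  out <- do.call(rbind, rows)
  if (all(!is.na(out$flag)))
    stop("every box size is flagged; no lacunarity computable", call. = FALSE)
  structure(out, roi = roi, class = c("lacunarity_curve", "data.frame"))
}

#' Scalar lacunarity score
#'
#' Aggregates a [lacunarity_curve()] to one number per scan: `mean_log`
#' (default) is the mean of log(Lambda) over unflagged box sizes, which
#' stabilises the mixing of scales; `at_fixed_box` reports Lambda at one
#' configured box size.
#'
#' @param curve A [lacunarity_curve()].
#' @param aggregation "mean_log" or "at_fixed_box".
#' @param box_size Box size used when `aggregation = "at_fixed_box"`.
#' @return List: `value`, `aggregation`, `roi`.
#' @export
lacunarity_score <- function(curve, aggregation = c("mean_log", "at_fixed_box"),
                             box_size = 4) {
  aggregation <- match.arg(aggregation)
  ok <- is.na(curve$flag) & is.finite(curve$lambda)
  if (!any(ok)) stop("no unflagged box sizes in curve", call. = FALSE)
  value <- if (aggregation == "mean_log") {
    mean(log(curve$lambda[ok]))
  } else {
    row <- which(ok & curve$box_size == box_size)
    if (!length(row))
      stop(sprintf("box_size %d not present/unflagged in curve", box_size),
           call. = FALSE)
    curve$lambda[row]
  }
  list(value = value, aggregation = aggregation,
       roi = attr(curve, "roi"))
}
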