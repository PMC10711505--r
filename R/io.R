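#' @name io
#' @title Image and table I/O
#' @description
#' NIfTI-1 is the image interchange format: multi-echo images are 4-D
#' volumes with a JSON sidecar carrying echo times (ms), TR and the
#' simulation provenance (noise model, sigma, seed); masks and maps are 3-D
#' volumes on the same grid. Voxel sizes live in the NIfTI header (pixdim)
#' and all per-voxel arithmetic uses them; readers reject inconsistent
#' metadata rather than silently reinterpreting it. Tables are plain CSV
#' (comma-separated, UTF-8, header row, missing values empty); models are
#' JSON.
NULL

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Write / read a multi-echo image as NIfTI-1 plus JSON sidecar
#'
#' @param image A [multiecho_image()].
#' @param path Output path ending in `.nii` or `.nii.gz`; the sidecar is
#'   written next to it with extension `.json`.
#' @return `write_multiecho` invisibly returns `path`; `read_multiecho`
#'   returns a [multiecho_image()].
#' @export
write_multiecho <- function(image, path) {
  nii <- RNifti::asNifti(image$data)
  RNifti::pixdim(nii) <- c(image$voxel_size, 1)
  RNifti::writeNifti(nii, path)
  side <- c(list(echo_times = image$echo_times), image$meta)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_multiecho
#' @export
read_multiecho <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop(sprintf("missing JSON sidecar for %s (expected %s)", path, sp),
         call. = FALSE)
  nii <- RNifti::readNifti(path)
  a <- array(as.vector(nii), dim = dim(nii))
  if (length(dim(a)) != 4L)
    stop(sprintf("%s: expected 4-D multi-echo image, got %d-D", path,
                 length(dim(a))), call. = FALSE)
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  te <- as.numeric(side$echo_times)
  if (length(te) != dim(a)[4])
    stop(sprintf("%s: %d echo volumes but sidecar lists %d echo times",
                 path, dim(a)[4], length(te)), call. = FALSE)
  vox <- RNifti::pixdim(nii)[1:3]
  meta <- side[setdiff(names(side), "echo_times")]
  multiecho_image(a, te, vox, meta = meta)
}

#' Write / read a lung label mask as 3-D NIfTI-1
#'
#' @param mask A [lung_mask()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @param expected_grid Optional list with `dim` and/or `voxel_size` that the
#'   file must match (voxel size within 1e-4 mm).
#' @return `write_mask` invisibly returns `path`; `read_mask` returns a
#'   [lung_mask()].
#' @export
write_mask <- function(mask, path) {
  nii <- RNifti::asNifti(array(as.integer(mask$labels), dim = dim(mask$labels)))
  RNifti::pixdim(nii) <- mask$voxel_size
  RNifti::writeNifti(nii, path, datatype = "int16")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, expected_grid = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  nii <- RNifti::readNifti(path)
  a <- array(as.vector(nii), dim = dim(nii))
  if (length(dim(a)) != 3L)
    stop(sprintf("%s: expected 3-D mask, got %d-D", path, length(dim(a))),
         call. = FALSE)
  if (any(a != round(a)))
    stop(path, ": mask is not integer-valued", call. = FALSE)
  vox <- RNifti::pixdim(nii)[1:3]
  if (!is.null(expected_grid)) {
    if (!is.null(expected_grid$dim))
      stopifnot_same_grid(dim(a), expected_grid$dim, paste0(path, " and expected grid"))
    if (!is.null(expected_grid$voxel_size) &&
        any(abs(vox - expected_grid$voxel_size) > 1e-4))
      stop(sprintf("%s: voxel size %s differs from expected %s", path,
                   paste(signif(vox, 6), collapse = "x"),
                   paste(expected_grid$voxel_size, collapse = "x")),
           call. = FALSE)
  }
  lung_mask(array(as.integer(a), dim = dim(a)), vox)
}

#' Cohort table CSV I/O
#'
#' Fixed dialect: comma-separated, UTF-8, header row, missing values empty.
#'
#' @param cohort Cohort data frame.
#' @param path CSV path.
#' @return `write_cohort` invisibly returns `path`; `read_cohort` the data
#'   frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Normative model JSON I/O
#'
#' @param model A [normative_model()].
#' @param path JSON path.
#' @return `write_model` invisibly returns `path`; `read_model` the
#'   [normative_model()].
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  normative_model(x$mean_slope, x$mean_intercept, x$sd_slope, x$sd_intercept,
                  x$ga_domain, metric = x$metric, source = x$source)
}
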