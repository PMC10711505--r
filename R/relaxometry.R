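#' @name relaxometry
#' @title Voxelwise mono-exponential T2* estimation
#' @description
#' Estimation of S0 and T2* per voxel from multi-echo magnitude data under
#' S(TE) = S0 * exp(-TE / T2*). Two fitters are provided:
#' \describe{
#'   \item{log-linear}{ordinary least squares of log(signal) on TE; fast and
#'     closed-form but biased under Rician noise at low SNR.}
#'   \item{nlls}{bounded Levenberg-Marquardt non-linear least squares in the
#'     signal domain, initialised from the log-linear solution; the field
#'     standard and the package default.}
#' }
#' Non-positive samples are dropped before the log transform; a voxel with
#' fewer than 3 usable echoes fails (status `failed`) rather than raising, so
#' whole-map fitting always completes. T2* estimates are clamped to
#' `t2_bounds` (default \[1, 500\] ms; values outside are non-physical at 3 T)
#' with the clamping recorded in `status`; a non-decaying signal (slope >= 0)
#' is reported as `clamped_high`.
NULL

FIT_STATUS <- c(failed = 0L, ok = 1L, clamped_low = 2L, clamped_high = 3L)
status_name <- function(code) names(FIT_STATUS)[match(code, FIT_STATUS)]

#' Log-linear T2* fit of one decay curve
#'
#' @param signal Magnitudes at each echo.
#' @param echo_times Echo times (same units as the returned t2star; ms by
#'   convention).
#' @param t2_bounds Length-2 clamp range for t2star.
#' @return A list of class `fit_result`: `s0`, `t2star_ms`, `r_squared`,
#'   `status` ("ok", "clamped_low", "clamped_high" or "failed").
#' @examples
#' te <- c(13.8, 70.4, 127.0, 183.6, 240.2)
#' fit_loglinear(1000 * exp(-te / 66), te)
#' @rdname relaxometry
#' @export
fit_loglinear <- function(signal, echo_times, t2_bounds = c(1, 500)) {
  keep <- is.finite(signal) & signal > 0
  if (sum(keep) < 3L)
    return(fit_result(NA_real_, NA_real_, NA_real_, "failed"))
  x <- echo_times[keep]; y <- log(signal[keep])
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  slope <- sum((x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  ss_tot <- sum((y - yb)^2)
  ss_res <- sum((y - intercept - slope * x)^2)
  r2 <- if (ss_tot > 0) max(0, 1 - ss_res / ss_tot) else 1
  s0 <- exp(intercept)
  if (slope >= 0)  # non-decaying signal
    return(fit_result(s0, t2_bounds[2], r2, "clamped_high"))
  t2 <- -1 / slope
  status <- "ok"
  if (t2 < t2_bounds[1]) { t2 <- t2_bounds[1]; status <- "clamped_low" }
  if (t2 > t2_bounds[2]) { t2 <- t2_bounds[2]; status <- "clamped_high" }
  fit_result(s0, t2, r2, status)
}

fit_result <- function(s0, t2star_ms, r_squared, status) {
  structure(list(s0 = s0, t2star_ms = t2star_ms, r_squared = r_squared,
                 status = status), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("T2* fit [%s]: s0 = %.4g, t2star = %.4g ms, R^2 = %.4f\n",
              x$status, x$s0, x$t2star_ms, x$r_squared))
  invisible(x)
}

#' Bounded non-linear least-squares T2* fit
#'
#' Minimises the signal-domain sum of squares over s0 > 0 and t2star within
#' `t2_bounds`, via Levenberg-Marquardt (minpack.lm), initialised from
#' `init` (the log-linear solution by default). If the optimiser fails the
#' initial solution is returned; the reported solution never has a larger
#' residual sum of squares than its initialisation. `r_squared` is computed
#' in the signal domain.
#'
#' @param signal,echo_times,t2_bounds As in [fit_loglinear()].
#' @param init Optional `fit_result` used as the starting point.
#' @rdname relaxometry
#' @export
fit_nlls <- function(signal, echo_times, init = NULL, t2_bounds = c(1, 500)) {
  keep <- is.finite(signal) & signal > 0
  if (sum(keep) < 3L)
    return(fit_result(NA_real_, NA_real_, NA_real_, "failed"))
  if (is.null(init)) init <- fit_loglinear(signal, echo_times, t2_bounds)
  if (init$status == "failed")
    return(fit_result(NA_real_, NA_real_, NA_real_, "failed"))
  x <- echo_times[keep]; y <- signal[keep]
  s0_0 <- max(init$s0, .Machine$double.eps)
  t2_0 <- min(max(init$t2star_ms, t2_bounds[1]), t2_bounds[2])
  ssr <- function(s0, t2) sum((y - s0 * exp(-x / t2))^2)
  best <- c(s0 = s0_0, t2 = t2_0)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ s0 * exp(-x / t2),
                      start = list(s0 = s0_0, t2 = t2_0),
                      lower = c(s0 = 1e-12, t2 = t2_bounds[1]),
                      upper = c(s0 = Inf, t2 = t2_bounds[2]),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(fit)) {
    cand <- stats::coef(fit)
    if (ssr(cand[["s0"]], cand[["t2"]]) <= ssr(best[["s0"]], best[["t2"]]))
      best <- c(s0 = cand[["s0"]], t2 = cand[["t2"]])
  }
  status <- "ok"
  if (best[["t2"]] <= t2_bounds[1]) status <- "clamped_low"
  if (best[["t2"]] >= t2_bounds[2]) status <- "clamped_high"
  ss_res <- ssr(best[["s0"]], best[["t2"]])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) max(0, 1 - ss_res / ss_tot) else 1
  fit_result(best[["s0"]], best[["t2"]], r2, status)
}

#' Fit a whole T2* map
#'
#' Applies the chosen fitter to every voxel inside `mask` (the whole grid if
#' no mask is given). The log-linear path is vectorised over voxels whose
#' echoes are all positive; remaining voxels fall back to the per-voxel
#' routine. Deterministic given its inputs.
#'
#' @param image A [multiecho_image()].
#' @param mask Optional logical/0-1 volume on the image grid restricting the
#'   fit.
#' @param method "nlls" (default) or "loglinear".
#' @param t2_bounds Clamp range in the units of `image$echo_times`.
#' @return An object of class `t2star_map`: volumes `t2star`, `s0`,
#'   `r_squared`, integer `status` (0 failed / 1 ok / 2 clamped_low /
#'   3 clamped_high), plus `voxel_size`, `method`, `t2_bounds`.
#' @export
fit_map <- function(image, mask = NULL, method = c("nlls", "loglinear"),
                    t2_bounds = c(1, 500)) {
  method <- match.arg(method)
  dims <- dim(image$data)[1:3]
  if (!is.null(mask)) {
    stopifnot_same_grid(dim(mask), dims, "mask and image")
    sel <- which(as.logical(mask))
  } else sel <- seq_len(prod(dims))

  te <- image$echo_times
  n_echo <- length(te)
  flat <- matrix(image$data, nrow = prod(dims), ncol = n_echo)

  t2v <- array(NA_real_, dims); s0v <- array(NA_real_, dims)
  r2v <- array(NA_real_, dims)
  stv <- array(FIT_STATUS[["failed"]], dims)
  if (length(sel) == 0L)
    return(t2star_map(t2v, s0v, r2v, stv, image$voxel_size, method, t2_bounds))

  S <- flat[sel, , drop = FALSE]
  allpos <- rowSums(is.finite(S) & S > 0) == n_echo

  # vectorised log-linear OLS for the all-positive voxels
  if (any(allpos)) {
    Y <- log(S[allpos, , drop = FALSE])
    xb <- mean(te); xc <- te - xb; sxx <- sum(xc^2)
    slope <- as.numeric(Y %*% xc) / sxx
    intercept <- rowMeans(Y) - slope * xb
    resid <- Y - outer(intercept, rep(1, n_echo)) - outer(slope, te)
    ss_res <- rowSums(resid^2)
    ss_tot <- rowSums((Y - rowMeans(Y))^2)
    r2 <- ifelse(ss_tot > 0, pmax(0, 1 - ss_res / ss_tot), 1)
    s0 <- exp(intercept)
    t2 <- ifelse(slope < 0, -1 / slope, t2_bounds[2])
    st <- rep(FIT_STATUS[["ok"]], length(t2))
    st[slope >= 0 | t2 > t2_bounds[2]] <- FIT_STATUS[["clamped_high"]]
    st[t2 < t2_bounds[1]] <- FIT_STATUS[["clamped_low"]]
    t2 <- pmin(pmax(t2, t2_bounds[1]), t2_bounds[2])

    if (method == "nlls") {
      idx <- which(allpos)
      for (j in seq_along(idx)) {
        init <- fit_result(s0[j], t2[j],
                           r2[j], status_name(st[j]))
        fr <- fit_nlls(S[idx[j], ], te, init = init, t2_bounds = t2_bounds)
        s0[j] <- fr$s0; t2[j] <- fr$t2star_ms; r2[j] <- fr$r_squared
        st[j] <- FIT_STATUS[[fr$status]]
      }
    }
    vox <- sel[allpos]
    t2v[vox] <- t2; s0v[vox] <- s0; r2v[vox] <- r2; stv[vox] <- st
  }

  # voxels with dropped echoes: per-voxel path
  for (i in which(!allpos)) {
    fr <- if (method == "nlls") fit_nlls(S[i, ], te, t2_bounds = t2_bounds)
          else fit_loglinear(S[i, ], te, t2_bounds = t2_bounds)
    vox <- sel[i]
    t2v[vox] <- fr$t2star_ms; s0v[vox] <- fr$s0; r2v[vox] <- fr$r_squared
    stv[vox] <- FIT_STATUS[[fr$status]]
  }
  t2star_map(t2v, s0v, r2v, stv, image$voxel_size, method, t2_bounds)
}

t2star_map <- function(t2star, s0, r_squared, status, voxel_size, method,
                       t2_bounds) {
  structure(list(t2star = t2star, s0 = s0, r_squared = r_squared,
                 status = status, voxel_size = voxel_size, method = method,
                 t2_bounds = t2_bounds),
            class = "t2star_map")
}

#' @export
print.t2star_map <- function(x, ...) {
  ok <- x$status != FIT_STATUS[["failed"]]
  cat(sprintf("T2* map %s (%s fit): %d fitted voxels, median T2* %.1f ms\n",
              paste(dim(x$t2star), collapse = "x"), x$method, sum(ok),
              stats::median(x$t2star[ok])))
  invisible(x)
}

#' Fit-quality voxel mask
#'
#' @param map A [fit_map()] result.
#' @param r2_min Minimum r-squared (>= 0; a value above 1 is unsatisfiable
#'   and yields an empty mask).
#' @param statuses_allowed Character vector of acceptable fit statuses.
#' @return Logical volume: voxels whose status is allowed and whose
#'   r_squared is at least `r2_min`.
#' @export
quality_mask <- function(map, r2_min = 0,
                         statuses_allowed = c("ok", "clamped_low", "clamped_high")) {
  if (r2_min < 0) stop("r2_min must be >= 0", call. = FALSE)
  bad <- setdiff(statuses_allowed, names(FIT_STATUS))
  if (length(bad)) stop("unknown statuses: ", paste(bad, collapse = ", "), call. = FALSE)
  codes <- FIT_STATUS[statuses_allowed]
  ok <- array(map$status %in% codes, dim = dim(map$status))
  ok & !is.na(map$r_squared) & map$r_squared >= r2_min
}
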