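#' Construct a normative model
#'
#' A normative model describes the reference mean and standard deviation of a
#' metric as linear functions of gestational age (GA):
#' mean(ga) = mean_slope * ga + mean_intercept and
#' sd(ga) = sd_slope * ga + sd_intercept. It powers z-scores and centiles.
#'
#' @param mean_slope,mean_intercept Coefficients of the mean function
#'   (metric units per week; metric units).
#' @param sd_slope,sd_intercept Coefficients of the SD function.
#' @param ga_domain Length-2 numeric, the GA range (weeks) over which the
#'   model is valid. The SD function must be positive throughout it.
#' @param metric Name of the modelled metric.
#' @param source Free-text provenance string.
#' @return An object of class `normative_model`.
#' @export
normative_model <- function(mean_slope, mean_intercept, sd_slope, sd_intercept,
                            ga_domain, metric = "t2star_ms", source = "user") {
  ga_domain <- as.numeric(ga_domain)
  if (length(ga_domain) != 2L || ga_domain[1] >= ga_domain[2])
    stop("ga_domain must be an increasing length-2 range", call. = FALSE)
  sd_ends <- sd_slope * ga_domain + sd_intercept
  # linear SD: positivity at both ends implies positivity throughout
  if (any(sd_ends <= 0))
    stop("SD function must be positive over the whole ga_domain", call. = FALSE)
  structure(list(mean_slope = as.numeric(mean_slope),
                 mean_intercept = as.numeric(mean_intercept),
                 sd_slope = as.numeric(sd_slope),
                 sd_intercept = as.numeric(sd_intercept),
                 ga_domain = ga_domain,
                 metric = as.character(metric),
                 source = as.character(source)),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("Normative model for %s [%s]\n", x$metric, x$source))
  cat(sprintf("  mean(ga) = %.6f * ga + %.6f\n", x$mean_slope, x$mean_intercept))
  cat(sprintf("  sd(ga)   = %.6f * ga + %.6f\n", x$sd_slope, x$sd_intercept))
  cat(sprintf("  GA domain: [%.1f, %.1f] weeks\n", x$ga_domain[1], x$ga_domain[2]))
  invisible(x)
}

#' Published fetal lung T2* normative model
#'
#' The reference model for mean fetal lung T2* (ms, both lungs) as a function
#' of gestational age, with printed coefficients
#' mean(ga) = 1.488884 * ga + 21.997645 and sd(ga) = 1.488884 * ga - 18.451005,
#' valid over the study GA range 20.6-38.3 weeks (the SD line is negative
#' below ~12.4 weeks, so the domain matters).
#'
#' @return A [normative_model()] object.
#' @examples
#' m <- published_model()
#' normative_mean(m, 30)   # reference mean T2* at 30 weeks
#' @export
published_model <- function() {
  normative_model(mean_slope = 1.488884, mean_intercept = 21.997645,
                  sd_slope = 1.488884, sd_intercept = -18.451005,
                  ga_domain = c(20.6, 38.3),
                  metric = "t2star_ms", source = "published")
}

#' Evaluate a normative model's mean or SD function
#'
#' @param model A [normative_model()].
#' @param ga_weeks Gestational ages (weeks).
#' @param check_domain If TRUE (default), error on GA outside the model domain.
#' @return Numeric vector of means (or SDs) in metric units.
#' @export
normative_mean <- function(model, ga_weeks, check_domain = TRUE) {
  if (check_domain) check_ga_domain(model, ga_weeks)
  model$mean_slope * ga_weeks + model$mean_intercept
}

#' @rdname normative_mean
#' @export
normative_sd <- function(model, ga_weeks, check_domain = TRUE) {
  if (check_domain) check_ga_domain(model, ga_weeks)
  model$sd_slope * ga_weeks + model$sd_intercept
}

check_ga_domain <- function(model, ga_weeks) {
  bad <- ga_weeks < model$ga_domain[1] | ga_weeks > model$ga_domain[2]
  if (any(bad))
    stop(sprintf("gestational age outside model domain [%.1f, %.1f] weeks",
                 model$ga_domain[1], model$ga_domain[2]), call. = FALSE)
  invisible(TRUE)
}

#' Convert an observation to a z-score and centile
#'
#' z = (observed - mean(ga)) / sd(ga); centile = 100 * pnorm(z), the exact
#' normal-CDF conversion.
#'
#' @param observed Observed metric value(s), in the model's metric units.
#' @param ga_weeks Gestational age(s) at observation, weeks; must lie in the
#'   model's domain.
#' @param model A [normative_model()].
#' @return A data frame with columns `z` and `centile`.
#' @examples
#' m <- published_model()
#' zscore(normative_mean(m, 30), 30, m)  # z = 0, centile = 50
#' @export
zscore <- function(observed, ga_weeks, model) {
  check_ga_domain(model, ga_weeks)
  z <- (observed - normative_mean(model, ga_weeks)) / normative_sd(model, ga_weeks)
  data.frame(z = z, centile = 100 * stats::pnorm(z))
}

#' Reference centile band table
#'
#' Tabulates value = mean(ga) + qnorm(centile/100) * sd(ga) over a GA grid,
#' for plotting reference charts.
#'
#' @param model A [normative_model()].
#' @param ga_grid GA values (weeks) inside the model domain.
#' @param centiles Centiles in (0, 100). Default c(3, 10, 50, 90, 97).
#' @return Data frame with columns `ga_weeks`, `centile`, `value`.
#' @export
reference_band <- function(model, ga_grid = NULL, centiles = c(3, 10, 50, 90, 97)) {
  if (is.null(ga_grid))
    ga_grid <- seq(model$ga_domain[1], model$ga_domain[2], length.out = 50)
  if (any(centiles <= 0 | centiles >= 100))
    stop("centiles must lie strictly between 0 and 100", call. = FALSE)
  check_ga_domain(model, ga_grid)
  grid <- expand.grid(ga_weeks = ga_grid, centile = centiles)
  grid$value <- normative_mean(model, grid$ga_weeks) +
    stats::qnorm(grid$centile / 100) * normative_sd(model, grid$ga_weeks)
  grid
}

#' Linear GA-trend regression for a cohort metric
#'
#' Ordinary least squares of a metric on gestational age. With
#' `cluster_by_subject = TRUE` the standard errors (and the slope p-value)
#' are made cluster-robust over `subject_id` to account for women scanned
#' more than once; point estimates are unchanged.
#'
#' @param cohort A cohort data frame with columns `subject_id`, `scan_id`,
#'   `ga_weeks` and the metric.
#' @param metric Name of the metric column.
#' @param cluster_by_subject Use cluster-robust (CR1-type) standard errors.
#' @return An object of class `trend_fit` with slope, intercept, r_squared,
#'   p_value, se_slope, n_scans, n_subjects and the underlying `lm` fit.
#' @export
fit_trend <- function(cohort, metric, cluster_by_subject = FALSE) {
  if (!metric %in% names(cohort))
    stop(sprintf("metric column '%s' not found", metric), call. = FALSE)
  d <- cohort[is.finite(cohort$ga_weeks) & is.finite(cohort[[metric]]), , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 scans with metric and GA", call. = FALSE)
  if (stats::var(d$ga_weeks) == 0) stop("gestational age is constant: singular design", call. = FALSE)
  fit <- stats::lm(stats::reformulate("ga_weeks", response = metric), data = d)
  co <- stats::coef(fit)
  if (cluster_by_subject) {
    vc <- sandwich::vcovCL(fit, cluster = d$subject_id, type = "HC1")
    ct <- lmtest::coeftest(fit, vcov. = vc)
    se_slope <- ct["ga_weeks", "Std. Error"]
    p_value <- ct["ga_weeks", "Pr(>|t|)"]
  } else {
    sm <- summary(fit)$coefficients
    se_slope <- sm["ga_weeks", "Std. Error"]
    p_value <- sm["ga_weeks", "Pr(>|t|)"]
  }
  structure(list(metric = metric,
                 slope = unname(co["ga_weeks"]),
                 intercept = unname(co["(Intercept)"]),
                 r_squared = summary(fit)$r.squared,
                 p_value = unname(p_value),
                 se_slope = unname(se_slope),
                 cluster_robust = cluster_by_subject,
                 n_scans = nrow(d),
                 n_subjects = length(unique(d$subject_id)),
                 lm_fit = fit),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("GA trend for %s (n=%d scans, %d subjects)\n",
              x$metric, x$n_scans, x$n_subjects))
  cat(sprintf("  slope = %.4f / week (SE %.4f%s), intercept = %.4f\n",
              x$slope, x$se_slope,
              if (x$cluster_robust) ", cluster-robust" else "", x$intercept))
  cat(sprintf("  R^2 = %.4f, p = %.3g\n", x$r_squared, x$p_value))
  invisible(x)
}

#' Estimate a linear SD-vs-GA function
#'
#' Two estimators of sd(ga) = sd_slope * ga + sd_intercept:
#' \describe{
#'   \item{abs_residual}{absolute residuals from the mean fit, scaled by
#'     sqrt(pi/2) (since E|N(0,s)| = s*sqrt(2/pi)), regressed on GA. Uses
#'     every scan.}
#'   \item{binned}{sample SD within GA bins (default: integer weeks),
#'     regressed on bin-centre GA. Requires several scans per bin.}
#' }
#'
#' @param cohort Cohort data frame.
#' @param metric Metric column name.
#' @param mean_fit A [fit_trend()] result for the same cohort/metric; fitted
#'   for you if omitted (abs_residual method only).
#' @param method `"abs_residual"` (default) or `"binned"`.
#' @return List with `sd_slope`, `sd_intercept`, `method` and
#'   `negative_sd_warning` (TRUE if the fitted SD line dips <= 0 anywhere on
#'   the cohort's GA range).
#' @export
fit_sd_trend <- function(cohort, metric, mean_fit = NULL,
                         method = c("abs_residual", "binned")) {
  method <- match.arg(method)
  d <- cohort[is.finite(cohort$ga_weeks) & is.finite(cohort[[metric]]), , drop = FALSE]
  if (method == "abs_residual") {
    if (is.null(mean_fit)) mean_fit <- fit_trend(d, metric)
    res <- d[[metric]] - (mean_fit$slope * d$ga_weeks + mean_fit$intercept)
    y <- abs(res) * sqrt(pi / 2)
    sfit <- stats::lm(y ~ d$ga_weeks)
    co <- stats::coef(sfit)
  } else {
    bin <- round(d$ga_weeks)
    sds <- tapply(d[[metric]], bin, stats::sd)
    keep <- !is.na(sds)
    if (sum(keep) < 3L) stop("need >= 3 GA bins with >= 2 scans", call. = FALSE)
    ga_bin <- as.numeric(names(sds))[keep]
    sfit <- stats::lm(sds[keep] ~ ga_bin)
    co <- stats::coef(sfit)
  }
  sd_slope <- unname(co[2]); sd_intercept <- unname(co[1])
  rng <- range(d$ga_weeks)
  neg <- any(sd_slope * rng + sd_intercept <= 0)
  list(sd_slope = sd_slope, sd_intercept = sd_intercept,
       method = method, negative_sd_warning = neg)
}

#' Fit a full normative model from a cohort
#'
#' Convenience wrapper: [fit_trend()] for the mean plus [fit_sd_trend()] for
#' the SD, returning a [normative_model()] with the cohort's GA range as
#' domain.
#'
#' @inheritParams fit_sd_trend
#' @param cluster_by_subject Passed to [fit_trend()].
#' @return A [normative_model()].
#' @export
fit_normative <- function(cohort, metric, method = "abs_residual",
                          cluster_by_subject = FALSE) {
  mf <- fit_trend(cohort, metric, cluster_by_subject = cluster_by_subject)
  sf <- fit_sd_trend(cohort, metric, mean_fit = if (method == "abs_residual") mf else NULL,
                     method = method)
  normative_model(mean_slope = mf$slope, mean_intercept = mf$intercept,
                  sd_slope = sf$sd_slope, sd_intercept = sf$sd_intercept,
                  ga_domain = range(cohort$ga_weeks), metric = metric,
                  source = "fitted")
}
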