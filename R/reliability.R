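#' Absolute-agreement intraclass correlation, two-way model
#'
#' ICC for observer reliability under the two-way mixed-effects,
#' absolute-agreement definition. With n targets (rows) rated by k raters
#' (columns), the mean squares of the two-way ANOVA without replication are
#' MSR (rows), MSC (columns) and MSE (residual), and the single-measures
#' coefficient is
#' \deqn{ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)).}
#' Absolute agreement penalises systematic offsets between raters (unlike
#' consistency-type ICC). The 95% confidence interval is the standard
#' F-based interval for this form (Satterthwaite degrees of freedom for the
#' lower-bound denominator). The average-measures coefficient ICC(A,k) is
#' obtained from the single-measures form by the Spearman-Brown relation.
#'
#' Rows with missing values are dropped (complete cases), with the dropped
#' count reported. A matrix with zero between-target variance has an
#' undefined coefficient and is flagged degenerate; identical rater columns
#' give ICC exactly 1.
#'
#' @param values Numeric n x k matrix (n targets >= 2, k raters >= 2).
#' @param type "single" (default) for ICC(A,1) or "average" for ICC(A,k).
#' @param conf_level Confidence level, default 0.95.
#' @return List of class `icc_result`: `icc`, `ci_low`, `ci_high`, `type`,
#'   `n_targets`, `k_raters`, `n_dropped`, `degenerate`.
#' @examples
#' m <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
#' icc_a1(m)
#' @export
icc_a1 <- function(values, type = c("single", "average"), conf_level = 0.95) {
  type <- match.arg(type)
  values <- as.matrix(values)
  cc <- stats::complete.cases(values)
  n_dropped <- sum(!cc)
  X <- values[cc, , drop = FALSE]
  n <- nrow(X); k <- ncol(X)
  if (n < 2L || k < 2L)
    stop("need >= 2 complete targets and >= 2 raters", call. = FALSE)

  gm <- mean(X)
  rm_ <- rowMeans(X); cm <- colMeans(X)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  mse <- sum((X - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm)^2) /
    ((n - 1) * (k - 1))

  if (msr == 0) {
    return(structure(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          type = type, n_targets = n, k_raters = k,
                          n_dropped = n_dropped, degenerate = TRUE),
                     class = "icc_result"))
  }
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    lo1 <- hi1 <- 1  # exact agreement
  } else {
    # McGraw & Wong F-based interval for ICC(A,1)
    r <- icc1
    a <- (k * r) / (n * (1 - r)); b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo1 <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi1 <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    lo1 <- max(-1, min(lo1, icc1)); hi1 <- min(1, max(hi1, icc1))
  }
  if (type == "single") {
    icc <- icc1; lo <- lo1; hi <- hi1
  } else {
    sb <- function(r) r * k / (1 + (k - 1) * r)
    icc <- sb(icc1); lo <- sb(lo1); hi <- sb(hi1)
  }
  structure(list(icc = icc, ci_low = lo, ci_high = hi, type = type,
                 n_targets = n, k_raters = k, n_dropped = n_dropped,
                 degenerate = FALSE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (x$degenerate) {
    cat("ICC undefined: zero between-target variance\n")
  } else {
    cat(sprintf("ICC(A,%s) = %.4f (95%% CI %.4f-%.4f), n=%d targets, k=%d raters\n",
                if (x$type == "single") "1" else "k", x$icc, x$ci_low,
                x$ci_high, x$n_targets, x$k_raters))
  }
  invisible(x)
}

#' Observer agreement report across metrics
#'
#' Matches two observers' cohort tables by `scan_id` and computes an
#' absolute-agreement ICC per metric over the matched scans.
#'
#' @param cohort_a,cohort_b Cohort data frames with `scan_id` and the metric
#'   columns; e.g. the same scans measured by two observers.
#' @param metrics Character vector of metric column names present in both.
#' @param type Passed to [icc_a1()].
#' @return Data frame, one row per metric: `metric`, `icc`, `ci_low`,
#'   `ci_high`, `n_scans`; attribute `n_unmatched` counts scan ids present
#'   in only one table.
#' @export
agreement_report <- function(cohort_a, cohort_b, metrics, type = "single") {
  shared <- intersect(cohort_a$scan_id, cohort_b$scan_id)
  if (!length(shared)) stop("no overlapping scan_ids", call. = FALSE)
  n_unmatched <- length(setdiff(union(cohort_a$scan_id, cohort_b$scan_id), shared))
  ia <- match(shared, cohort_a$scan_id)
  ib <- match(shared, cohort_b$scan_id)
  rows <- lapply(metrics, function(m) {
    if (!m %in% names(cohort_a) || !m %in% names(cohort_b))
      stop(sprintf("metric '%s' missing from a cohort table", m), call. = FALSE)
    res <- icc_a1(cbind(cohort_a[[m]][ia], cohort_b[[m]][ib]), type = type)
    data.frame(metric = m, icc = res$icc, ci_low = res$ci_low,
               ci_high = res$ci_high, n_scans = res$n_targets)
  })
  structure(do.call(rbind, rows), n_unmatched = n_unmatched)
}
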