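#' Cohort simulation specification
#'
#' Describes the generative model for a synthetic scan cohort: the
#' gestational-age (GA) distribution, the normative model generating the
#' metric, and the fraction of subjects scanned twice. Defaults reproduce the
#' study design: GA summarised by mean 29.9, SD 4.3 weeks over the range
#' 20.6-38.3, and 10 of 87 women with a second scan.
#'
#' GA values are drawn from a truncated normal on \[ga_min, ga_max\]. Because
#' truncation changes moments, the parent mean/SD are calibrated (by
#' numerical moment matching over the full generative scheme, including
#' repeat scans) so that the scan-level GA distribution has expectation
#' `ga_mean` and standard deviation `ga_sd` — the generator is required to
#' match the cohort summary statistics, not to use them as parent
#' parameters.
#'
#' @param n_subjects Number of subjects (>= 0).
#' @param ga_mean,ga_sd Target scan-level GA mean and SD (weeks).
#' @param ga_min,ga_max GA range (weeks), ga_min < ga_max.
#' @param model [normative_model()] generating the metric; its SD function
#'   must be positive over \[ga_min, ga_max\].
#' @param repeat_scan_fraction Fraction of subjects receiving a second scan
#'   at GA + U(2, 8) weeks (clipped to the range). Default 10/87.
#' @return An object of class `cohort_spec` (includes the calibrated parent
#'   GA parameters `parent_mean`, `parent_sd`).
#' @export
cohort_spec <- function(n_subjects = 87,
                        ga_mean = 29.9, ga_sd = 4.3,
                        ga_min = 20.6, ga_max = 38.3,
                        model = published_model(),
                        repeat_scan_fraction = 10 / 87) {
  if (n_subjects < 0) stop("n_subjects must be >= 0", call. = FALSE)
  if (ga_min >= ga_max) stop("ga_min must be < ga_max", call. = FALSE)
  if (repeat_scan_fraction < 0 || repeat_scan_fraction > 1)
    stop("repeat_scan_fraction must lie in [0, 1]", call. = FALSE)
  sd_ends <- normative_sd(model, c(ga_min, ga_max), check_domain = FALSE)
  if (any(sd_ends <= 0))
    stop("normative SD function must be positive over [ga_min, ga_max]",
         call. = FALSE)
  parent <- calibrate_ga_parent(ga_mean, ga_sd, ga_min, ga_max,
                                repeat_scan_fraction)
  structure(list(n_subjects = as.integer(n_subjects),
                 ga_mean = ga_mean, ga_sd = ga_sd,
                 ga_min = ga_min, ga_max = ga_max,
                 model = model,
                 repeat_scan_fraction = repeat_scan_fraction,
                 parent_mean = parent[1], parent_sd = parent[2]),
            class = "cohort_spec")
}

# Truncated-normal moments on [lo, hi] for parent N(mu, sigma).
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

# Scan-level GA moments under the full scheme: first scans from the
# truncated normal, a fraction of subjects rescanned at min(GA + U(2,8), hi).
# Computed by quadrature over the truncated density and the uniform delta.
scan_level_moments <- function(mu, sigma, lo, hi, repeat_fraction) {
  first <- truncnorm_moments(mu, sigma, lo, hi)
  if (repeat_fraction == 0) return(first)
  ng <- 801L; nd <- 61L
  g <- seq(lo, hi, length.out = ng)
  w <- stats::dnorm(g, mu, sigma) / (stats::pnorm(hi, mu, sigma) - stats::pnorm(lo, mu, sigma))
  w <- w / sum(w)
  d <- seq(2, 8, length.out = nd)
  wd <- rep(1 / nd, nd)
  R <- pmin(outer(g, d, `+`), hi)
  m2_1 <- as.numeric(t(w) %*% R %*% wd)          # E[repeat GA]
  m2_2 <- as.numeric(t(w) %*% (R^2) %*% wd)      # E[repeat GA^2]
  p <- repeat_fraction / (1 + repeat_fraction)   # fraction of scans that are repeats
  m1_2 <- first["sd"]^2 + first["mean"]^2
  mean_mix <- (1 - p) * first[["mean"]] + p * m2_1
  m2_mix <- (1 - p) * m1_2 + p * m2_2
  c(mean = mean_mix, sd = sqrt(m2_mix - mean_mix^2))
}

# Solve for parent (mu, sigma) so the scan-level GA moments hit the targets.
calibrate_ga_parent <- function(ga_mean, ga_sd, lo, hi, repeat_fraction) {
  obj <- function(p) {
    m <- scan_level_moments(p[1], exp(p[2]), lo, hi, repeat_fraction)
    sum((m - c(ga_mean, ga_sd))^2)
  }
  fit <- stats::optim(c(ga_mean, log(ga_sd)), obj,
                      control = list(reltol = 1e-14, maxit = 5000))
  if (fit$value > 1e-6)
    warning("GA moment calibration did not fully converge; moments may be off")
  c(fit$par[1], exp(fit$par[2]))
}

# Inverse-CDF sampler for the truncated normal (deterministic given RNG).
rtruncnorm <- function(n, mu, sigma, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mu, sigma), stats::pnorm(hi, mu, sigma))
  stats::qnorm(u, mu, sigma)
}

#' Simulate a normative scan cohort
#'
#' Draws a cohort table under a [cohort_spec()]: one first scan per subject
#' with GA from the calibrated truncated normal, a second scan for a
#' fraction of subjects at GA + U(2, 8) weeks (clipped to the GA range), and
#' a metric value per scan drawn from Normal(mean(GA), SD(GA)) under the
#' spec's normative model.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer RNG seed.
#' @return A data frame with columns `subject_id`, `scan_id`, `ga_weeks` and
#'   the metric (named after `spec$model$metric`); zero rows but full schema
#'   when `n_subjects = 0`.
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_subjects = 20), seed = 7)
#' head(coh)
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  metric <- spec$model$metric
  empty <- data.frame(subject_id = character(), scan_id = character(),
                      ga_weeks = numeric(), metric = numeric())
  names(empty)[4] <- metric
  if (spec$n_subjects == 0L) return(empty)
  with_seed(seed, {
    n <- spec$n_subjects
    ga1 <- rtruncnorm(n, spec$parent_mean, spec$parent_sd, spec$ga_min, spec$ga_max)
    n_rep <- round(spec$repeat_scan_fraction * n)
    rep_idx <- if (n_rep > 0) sample.int(n, n_rep) else integer()
    delta <- stats::runif(n_rep, 2, 8)
    ga2 <- pmin(pmax(ga1[rep_idx] + delta, spec$ga_min), spec$ga_max)
    subject <- c(sprintf("S%03d", seq_len(n)), sprintf("S%03d", rep_idx))
    scan <- c(sprintf("S%03d_1", seq_len(n)), sprintf("S%03d_2", rep_idx))
    ga <- c(ga1, ga2)
    mu <- normative_mean(spec$model, ga, check_domain = FALSE)
    sdv <- normative_sd(spec$model, ga, check_domain = FALSE)
    value <- stats::rnorm(length(ga), mu, sdv)
    out <- data.frame(subject_id = subject, scan_id = scan, ga_weeks = ga,
                      metric = value)
    names(out)[4] <- metric
    out[order(out$scan_id), , drop = FALSE]
  })
}
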