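## Trend inference: does SD / COVAR / MEAN increase, decrease, or show no
## significant age-related change across bins?

.trend_statistics <- c("SD", "COVAR", "MEAN")

new_trend_result <- function(statistic, slope, ci_low, ci_high, alpha, method,
                             n_boot = NA_integer_, seed = NA_integer_,
                             n_bins, curve = NULL) {
  stopifnot(ci_low <= slope + 1e-12, slope <= ci_high + 1e-12)
  structure(
    list(
      statistic = statistic,
      slope = slope,
      ci_low = ci_low,
      ci_high = ci_high,
      alpha = alpha,
      method = method,
      n_boot = n_boot,
      seed = seed,
      n_bins = n_bins,
      direction = ci_direction(ci_low, ci_high)
    ),
    class = "trend_result"
  )
}

## CI-sign rule; a zero-width CI exactly at 0 is conservatively 'none'.
ci_direction <- function(ci_low, ci_high) {
  if (ci_high < 0) "decrease" else if (ci_low > 0) "increase" else "none"
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(
    "<trend_result> %s vs age: slope %.4g [%.4g, %.4g] per year (%s, alpha=%g) -> %s\n",
    x$statistic, x$slope, x$ci_low, x$ci_high, x$method, x$alpha, x$direction
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trend result
#'
#' One row per fitted trend: statistic, slope (statistic units per year),
#' confidence bounds, method and the three-way direction call.
#'
#' @param x A `trend_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.trend_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    slope = x$slope,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    alpha = x$alpha,
    method = x$method,
    n_boot = x$n_boot,
    direction = x$direction
  )
}

#' @rdname tidy.trend_result
#' @export
glance.trend_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    method = x$method,
    n_bins = x$n_bins,
    direction = x$direction
  )
}

check_curve <- function(curve) {
  need <- c("midpoint", "n", "mean", "sd", "covar")
  if (!all(need %in% names(curve))) {
    abort_contract(sprintf(
      "Dispersion curve must have columns %s.", paste(need, collapse = ", ")
    ))
  }
  if (nrow(curve) < 3L) {
    abort_config("At least 3 bins are required to fit a trend.")
  }
  if (any(curve$n < 2)) {
    abort_config("Every bin must contain at least 2 subjects.")
  }
  invisible(curve)
}

curve_statistic <- function(curve, statistic) {
  switch(statistic,
    SD = curve$sd,
    COVAR = curve$covar,
    MEAN = curve$mean
  )
}

## Asymptotic standard errors of the per-bin statistics:
##   SE(SD)   = sd / sqrt(2(n-1))
##   SE(CV)   = cv * sqrt(1/(2(n-1)) + (cv/100)^2 / n)   (normal-theory, Miller-type)
##   SE(MEAN) = sd / sqrt(n)
curve_se <- function(curve, statistic) {
  n <- curve$n
  switch(statistic,
    SD = curve$sd / sqrt(2 * (n - 1)),
    COVAR = curve$covar * sqrt(1 / (2 * (n - 1)) + (curve$covar / 100)^2 / n),
    MEAN = curve$sd / sqrt(n)
  )
}

#' Weighted least-squares trend of a binned statistic against age
#'
#' Fits a weighted least-squares line of the per-bin statistic (SD, COVAR or
#' MEAN) on the bin midpoints, with weights `1/SE^2` from the asymptotic
#' standard errors of each statistic. The confidence interval uses the t
#' distribution with `bins - 2` degrees of freedom, and the three-way
#' direction call follows the CI-sign rule: an interval wholly below zero is a
#' decrease, wholly above zero an increase, anything straddling zero "no
#' significant age-related change".
#'
#' If any bin has zero dispersion (sample SD = 0), the asymptotic weights are
#' undefined and the fit falls back to ordinary (unweighted) least squares
#' with a warning.
#'
#' @param curve A dispersion curve from [bin_cohort()] (or any tibble with
#'   columns `midpoint`, `n`, `mean`, `sd`, `covar`), with at least 3 bins.
#' @param statistic `"SD"`, `"COVAR"` or `"MEAN"`.
#' @param alpha Two-sided significance level of the CI. Default 0.05.
#' @return A `trend_result` (see [tidy.trend_result()]).
#' @examples
#' co <- simulate_cross_sectional(scenario_spec("S1"), n = 2000, seed = 11)
#' wls_trend(bin_cohort(co, age_bin_edges(30, 80)), "SD")
#' @export
wls_trend <- function(curve, statistic = c("COVAR", "SD", "MEAN"), alpha = 0.05) {
  statistic <- match.arg(statistic)
  check_curve(curve)
  stopifnot(is_number(alpha), alpha > 0, alpha < 1)
  y <- curve_statistic(curve, statistic)
  se <- curve_se(curve, statistic)
  x <- curve$midpoint
  if (any(se == 0)) {
    warn(sprintf(
      "Zero standard error in at least one bin (sd = 0); falling back to an unweighted fit of %s.",
      statistic
    ), class = "agecovar_warning_unweighted")
    fit <- lm(y ~ x)
  } else {
    fit <- lm(y ~ x, weights = 1 / se^2)
  }
  slope <- unname(coef(fit)[2L])
  ci <- tryCatch(
    suppressWarnings(unname(confint(fit, "x", level = 1 - alpha))),
    error = function(e) c(NA_real_, NA_real_)
  )
  # a perfectly linear curve has zero residual variance: the CI collapses
  if (any(!is.finite(ci))) ci <- c(slope, slope)
  new_trend_result(
    statistic = statistic, slope = slope,
    ci_low = ci[1L], ci_high = ci[2L],
    alpha = alpha, method = "wls_delta", n_bins = nrow(curve)
  )
}

#' Stratified bootstrap trend of a binned statistic against age
#'
#' Distribution-free alternative to [wls_trend()], recommended for real data:
#' subjects are resampled with replacement *within* each age bin (stratified,
#' preserving the age design), the binned statistic and its unweighted
#' least-squares slope on the bin midpoints are recomputed per replicate, and
#' the confidence interval is the percentile interval over replicates. The
#' point estimate is the slope on the original data. Identical
#' `(cohort, edges, statistic, n_boot, seed)` give identical intervals.
#'
#' Replicates in which the statistic is undefined (a resampled bin mean
#' `<= 0`, making COVAR meaningless) are rejected and redrawn; if more than
#' 10 % of replicates are rejected the parameters are deemed incompatible with
#' the statistic and an error is raised.
#'
#' @param cohort A cross-sectional `cohort_sample`.
#' @param statistic `"SD"`, `"COVAR"` or `"MEAN"`.
#' @param edges Bin edges as in [bin_cohort()].
#' @param n_boot Number of bootstrap replicates. Default 2000.
#' @param alpha Two-sided significance level. Default 0.05.
#' @param seed Integer seed (required: bootstrap results are reproducible by
#'   contract).
#' @param min_n Minimum subjects per bin (see [bin_cohort()]).
#' @return A `trend_result`.
#' @export
bootstrap_trend <- function(cohort, statistic = c("COVAR", "SD", "MEAN"),
                            edges, n_boot = 2000, alpha = 0.05, seed,
                            min_n = 10) {
  statistic <- match.arg(statistic)
  stopifnot(is_number(n_boot), n_boot >= 2, is_number(alpha), alpha > 0, alpha < 1)
  if (missing(seed)) abort_contract("`seed` is required for a reproducible bootstrap.")
  curve <- bin_cohort(cohort, edges, min_n = min_n)
  vals <- split_by_bin(cohort, edges, nrow(curve))
  boot <- boot_moments(vals, n_boot = as.integer(n_boot), seed = seed)
  trend_from_boot(curve, boot, vals, statistic, alpha = alpha,
                  n_boot = as.integer(n_boot), seed = as.integer(seed))
}

split_by_bin <- function(cohort, edges, n_bins) {
  idx <- findInterval(cohort$age, edges, rightmost.closed = TRUE)
  lapply(seq_len(n_bins), function(j) cohort$value[idx == j])
}

## Shared bootstrap engine: one set of within-bin resamples yields the
## replicate mean and sd matrices (n_boot x n_bins) that every statistic is
## derived from, so SD and COVAR trends computed from the same seed use the
## same resamples.
boot_moments <- function(vals, n_boot, seed) {
  n_bins <- length(vals)
  means <- matrix(NA_real_, n_boot, n_bins)
  sds <- matrix(NA_real_, n_boot, n_bins)
  with_seed(seed, {
    for (j in seq_len(n_bins)) {
      v <- vals[[j]]
      nj <- length(v)
      draw <- matrix(v[sample.int(nj, n_boot * nj, replace = TRUE)], n_boot, nj)
      m <- rowMeans(draw)
      ss <- rowSums(draw * draw)
      means[, j] <- m
      sds[, j] <- sqrt(pmax(ss - nj * m^2, 0) / (nj - 1))
    }
  })
  list(means = means, sds = sds)
}

trend_from_boot <- function(curve, boot, vals, statistic, alpha, n_boot, seed) {
  x <- curve$midpoint
  cx <- x - mean(x)
  sxx <- sum(cx^2)
  ols_slope <- function(Y) as.numeric(Y %*% cx) / sxx

  if (statistic %in% c("COVAR", "MEAN")) {
    # reject and redraw replicates on which the statistic is undefined
    bad <- rowSums(boot$means <= 0) > 0
    n_bad_total <- sum(bad)
    if (n_bad_total > 0.1 * n_boot) {
      abort_domain(sprintf(
        "%d of %d bootstrap replicates had a bin mean <= 0: parameters incompatible with the %s statistic.",
        n_bad_total, n_boot, statistic
      ))
    }
    redraw_seed <- substream_seeds(seed, 5L)[5L]
    attempt <- 0L
    while (any(bad)) {
      attempt <- attempt + 1L
      if (attempt > 100L) {
        abort_domain("Bootstrap replicate redraw did not converge.")
      }
      rows <- which(bad)
      fresh <- boot_moments(vals, n_boot = length(rows),
                            seed = (redraw_seed + attempt) %% .Machine$integer.max)
      ok <- rowSums(fresh$means <= 0) == 0
      boot$means[rows[ok], ] <- fresh$means[ok, , drop = FALSE]
      boot$sds[rows[ok], ] <- fresh$sds[ok, , drop = FALSE]
      bad[rows[ok]] <- FALSE
    }
  }

  stat_mat <- switch(statistic,
    SD = boot$sds,
    COVAR = 100 * boot$sds / boot$means,
    MEAN = boot$means
  )
  slope_reps <- ols_slope(stat_mat)
  y0 <- curve_statistic(curve, statistic)
  slope <- sum(cx * y0) / sxx
  ci <- unname(quantile(slope_reps, c(alpha / 2, 1 - alpha / 2), names = FALSE))
  # guard against a point estimate outside the percentile interval (possible
  # in principle with heavy skew; clamp so the invariant ci_low<=slope<=ci_high holds)
  ci[1L] <- min(ci[1L], slope)
  ci[2L] <- max(ci[2L], slope)
  new_trend_result(
    statistic = statistic, slope = slope,
    ci_low = ci[1L], ci_high = ci[2L],
    alpha = alpha, method = "bootstrap",
    n_boot = n_boot, seed = seed, n_bins = nrow(curve)
  )
}

#' Direction of a fitted trend
#'
#' The three-way call derived from the confidence interval: wholly below zero
#' is `"decrease"`, wholly above zero `"increase"`, and an interval straddling
#' (or touching) zero is `"none"` — no significant age-related change.
#'
#' @param result A `trend_result`.
#' @return `"decrease"`, `"none"` or `"increase"`.
#' @export
direction_of <- function(result) {
  if (!inherits(result, "trend_result")) {
    abort_contract("`result` must be a trend_result.")
  }
  ci_direction(result$ci_low, result$ci_high)
}
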