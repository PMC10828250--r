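# Shared fixtures: default specs and small constructed cohorts/curves.

default_spec <- function(scenario, ...) scenario_spec(scenario, ...)

all_scenarios <- c("S1", "S2", "S3", "S4")

# Cross-sectional cohort built directly from (age, value) vectors.
make_cohort <- function(age, value, design = "cross_sectional") {
  agecovar:::new_cohort(
    tibble::tibble(
      subject_id = sprintf("m%04d", seq_along(age)),
      age = as.numeric(age),
      value = as.numeric(value)
    ),
    design = design, provenance = "constructed in test"
  )
}

# Dispersion curve built from analytic moments at bin midpoints, with a
# nominal per-bin n (for standard-error computation in trend fits).
analytic_curve <- function(spec, midpoints, n_per_bin) {
  m <- analytic_moments(spec, midpoints)
  tibble::tibble(
    bin_lo = midpoints - 5, bin_hi = midpoints + 5,
    midpoint = midpoints, n = n_per_bin,
    mean = m$mean, sd = m$sd, covar = m$covar
  )
}

# Trend result with a prescribed CI, for exercising the direction rule and
# the classification mapping without running a fit.
fake_trend <- function(statistic, ci_low, ci_high, slope = mean(c(ci_low, ci_high))) {
  agecovar:::new_trend_result(
    statistic = statistic, slope = slope, ci_low = ci_low, ci_high = ci_high,
    alpha = 0.05, method = "wls_delta", n_bins = 5L
  )
}
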