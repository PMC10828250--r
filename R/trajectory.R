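## Noise-free individual trajectories and closed-form population moments.

#' Evaluate an individual's noise-free trajectory
#'
#' Computes the value of the physiological function for one or more
#' individuals at given ages under a scenario's decline model. With
#' `tau = age - baseline_age` and `b` the individual's baseline:
#'
#' * S1: `b * (1 - relative_rate * tau)` — linear loss of a fixed fraction of
#'   the *baseline* per year (not compounding: 1 %/year from age 30 leaves
#'   exactly 50 % at age 80).
#' * S2: `b - absolute_rate * tau`.
#' * S3: `b - slope * tau`, with `slope` the individual's own decline rate.
#' * S4: `floor + (b - floor) * (1 - convergence_rate * tau)` — the gap above
#'   the common floor shrinks by a fixed fraction of its starting size per
#'   year, so the steepest losses go to the highest starting values.
#'
#' Values are never clipped: a combination of baseline, slope and age that
#' would drive the linear form negative raises a domain error naming the
#' subject and age, so the caller can choose parameters for which the model
#' is valid.
#'
#' @param spec A [scenario_spec()].
#' @param baseline Numeric vector of baseline values `b` (> 0; for S4,
#'   `>= convergence_floor`).
#' @param age Numeric vector of ages in `[baseline_age, max_age]`; recycled
#'   against `baseline`.
#' @param slope Individual decline rates (units/year, >= 0); required for S3,
#'   ignored otherwise.
#' @param subject Optional subject identifiers used in error messages.
#' @return Numeric vector of noise-free function values (>= 0).
#' @examples
#' trajectory_value(scenario_spec("S1"), baseline = 100, age = 80)  # 50
#' @export
trajectory_value <- function(spec, baseline, age, slope = NULL, subject = NULL) {
  validate_scenario_spec(spec)
  n <- max(length(baseline), length(age))
  baseline <- rep_len(baseline, n)
  age <- rep_len(age, n)
  subject <- if (is.null(subject)) as.character(seq_len(n)) else rep_len(subject, n)

  bad_age <- !is.finite(age) | age < spec$baseline_age | age > spec$max_age
  if (any(bad_age)) {
    i <- which(bad_age)[1L]
    abort_range(sprintf(
      "Age %g (subject %s) outside the modelled range [%g, %g].",
      age[i], subject[i], spec$baseline_age, spec$max_age
    ))
  }
  if (any(baseline <= 0)) {
    i <- which(baseline <= 0)[1L]
    abort_domain(sprintf("Baseline %g (subject %s) must be > 0.", baseline[i], subject[i]))
  }

  tau <- age - spec$baseline_age
  sid <- short_scenario(spec$scenario_id)
  value <- switch(sid,
    S1 = baseline * (1 - spec$relative_rate * tau),
    S2 = baseline - spec$absolute_rate * tau,
    S3 = {
      if (is.null(slope)) {
        abort_contract("Scenario S3 requires individual `slope` values.")
      }
      slope <- rep_len(slope, n)
      if (any(slope < 0)) abort_domain("S3 individual slopes must be >= 0.")
      baseline - slope * tau
    },
    S4 = {
      if (any(baseline < spec$convergence_floor)) {
        i <- which(baseline < spec$convergence_floor)[1L]
        abort_domain(sprintf(
          "S4 baseline %g (subject %s) lies below the convergence floor %g.",
          baseline[i], subject[i], spec$convergence_floor
        ))
      }
      spec$convergence_floor +
        (baseline - spec$convergence_floor) * (1 - spec$convergence_rate * tau)
    }
  )

  if (any(value < 0)) {
    i <- which(value < 0)[1L]
    abort_domain(sprintf(
      "Trajectory of subject %s reaches %.4g (< 0) at age %g under %s; choose parameters for which the linear decline stays non-negative.",
      subject[i], value[i], age[i], spec$scenario_id
    ))
  }
  value
}

#' Moments of a zero-truncated normal distribution
#'
#' Mean and SD of `N(mean, sd^2)` conditioned on being `>= 0`; used for the
#' S3 individual slope distribution, whose truncation keeps every trajectory
#' non-increasing.
#'
#' @param mean,sd Parent normal parameters (`sd >= 0`).
#' @return Named list with elements `mean` and `sd` of the truncated
#'   distribution.
#' @export
truncnorm_moments <- function(mean, sd) {
  if (sd == 0) {
    if (mean < 0) abort_config("Degenerate slope distribution entirely below 0.")
    return(list(mean = mean, sd = 0))
  }
  alpha <- -mean / sd
  z <- pnorm(alpha, lower.tail = FALSE)
  if (z <= 0) abort_config("Slope distribution has no mass above 0.")
  lambda <- dnorm(alpha) / z
  m <- mean + sd * lambda
  v <- sd^2 * (1 + alpha * lambda - lambda^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

#' Closed-form population moments at given ages
#'
#' Mean, SD and COVAR (coefficient of variation, `100 * SD / mean`, in %) of
#' the noise-free population value at each requested age, with
#' `tau = age - baseline_age` and `(mu_b, sigma_b)` the baseline moments:
#'
#' * S1: mean `mu_b (1 - r tau)`, SD `sigma_b (1 - r tau)` — COVAR constant.
#' * S2: mean `mu_b - d tau`, SD `sigma_b` — COVAR grows as the mean falls.
#' * S3: mean `mu_b - m_d tau`, SD `sqrt(sigma_b^2 + tau^2 s_d^2)`, where
#'   `(m_d, s_d)` are the moments of the *zero-truncated* slope distribution
#'   (slopes independent of baselines).
#' * S4: mean `c + (mu_b - c)(1 - k tau)`, SD `sigma_b (1 - k tau)`.
#'
#' The baseline distribution is treated as exactly normal; the truncation
#' applied when sampling baselines is assumed to carry negligible mass (the
#' constructor defaults guarantee this; see the methods vignette).
#'
#' @param spec A [scenario_spec()].
#' @param age Numeric vector of ages in `[baseline_age, max_age]`.
#' @return A tibble with columns `age`, `mean`, `sd`, `covar` (one row per
#'   age, input order preserved).
#' @examples
#' analytic_moments(scenario_spec("S1", baseline_mean = 80, baseline_sd = 20),
#'                  c(30, 55, 80))
#' @export
analytic_moments <- function(spec, age) {
  validate_scenario_spec(spec)
  bad <- !is.finite(age) | age < spec$baseline_age | age > spec$max_age
  if (any(bad)) {
    abort_range(sprintf(
      "Age %g outside the modelled range [%g, %g].",
      age[which(bad)[1L]], spec$baseline_age, spec$max_age
    ))
  }
  tau <- age - spec$baseline_age
  mu_b <- spec$baseline_mean
  sigma_b <- spec$baseline_sd
  sid <- short_scenario(spec$scenario_id)
  m <- switch(sid,
    S1 = list(mean = mu_b * (1 - spec$relative_rate * tau),
              sd = sigma_b * (1 - spec$relative_rate * tau)),
    S2 = list(mean = mu_b - spec$absolute_rate * tau,
              sd = rep_len(sigma_b, length(tau))),
    S3 = {
      tm <- truncnorm_moments(spec$slope_mean, spec$slope_sd)
      list(mean = mu_b - tm$mean * tau,
           sd = sqrt(sigma_b^2 + tau^2 * tm$sd^2))
    },
    S4 = list(
      mean = spec$convergence_floor +
        (mu_b - spec$convergence_floor) * (1 - spec$convergence_rate * tau),
      sd = sigma_b * (1 - spec$convergence_rate * tau)
    )
  )
  if (any(m$mean <= 0)) {
    abort_domain(sprintf(
      "Population mean non-positive at age %g; COVAR undefined.",
      age[which(m$mean <= 0)[1L]]
    ))
  }
  tibble::tibble(
    age = as.numeric(age),
    mean = m$mean,
    sd = m$sd,
    covar = 100 * m$sd / m$mean
  )
}

#' Moment curve over an ordered grid of ages
#'
#' Vectorised convenience around [analytic_moments()] for plotting and
#' tabulating the theoretical mean/SD/COVAR curves of a scenario.
#'
#' @param spec A [scenario_spec()].
#' @param ages Strictly increasing ages within `[baseline_age, max_age]`.
#' @return A tibble with columns `age`, `mean`, `sd`, `covar`.
#' @export
moment_trajectory <- function(spec, ages) {
  if (length(ages) < 1L || any(diff(ages) <= 0)) {
    abort_contract("`ages` must be a non-empty, strictly increasing vector.")
  }
  analytic_moments(spec, ages)
}
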