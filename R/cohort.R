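## Cohort simulation: individuals, cross-sectional and longitudinal designs.

new_cohort <- function(records, design, provenance) {
  stopifnot(design %in% c("cross_sectional", "longitudinal"))
  out <- tibble::as_tibble(records[c("subject_id", "age", "value")])
  structure(out,
    class = c("cohort_sample", class(out)),
    design = design,
    provenance = provenance
  )
}

#' Cohort design and provenance
#'
#' A cohort sample is a tibble with one observation per row (`subject_id`,
#' `age`, `value`) plus two attributes: the sampling design
#' (`"cross_sectional"`: every subject measured once; `"longitudinal"`: every
#' subject measured at two or more ages) and a free-text provenance string.
#'
#' @param cohort A `cohort_sample`.
#' @return A single string.
#' @export
cohort_design <- function(cohort) attr(cohort, "design") %||% "cross_sectional"

#' @rdname cohort_design
#' @export
cohort_provenance <- function(cohort) attr(cohort, "provenance") %||% "unknown"

#' @export
print.cohort_sample <- function(x, ...) {
  cat(sprintf(
    "<cohort_sample> %s, %d observations of %d subjects\n  provenance: %s\n",
    cohort_design(x), nrow(x), length(unique(x$subject_id)), cohort_provenance(x)
  ))
  NextMethod()
}

validate_cohort <- function(cohort, line_offset = 0L) {
  need <- c("subject_id", "age", "value")
  if (!all(need %in% names(cohort))) {
    abort_parse(sprintf(
      "Cohort must have columns %s.", paste(need, collapse = ", ")
    ))
  }
  if (nrow(cohort) == 0L) abort_parse("Empty cohort: no observations.")
  bad_age <- !is.finite(cohort$age) | cohort$age < 0
  if (any(bad_age)) {
    abort_parse(sprintf(
      "Invalid age at line %d: ages must be finite and >= 0.",
      which(bad_age)[1L] + line_offset
    ))
  }
  if (any(!is.finite(cohort$value))) {
    abort_parse(sprintf(
      "Non-finite value at line %d.", which(!is.finite(cohort$value))[1L] + line_offset
    ))
  }
  dup <- duplicated(cohort[c("subject_id", "age")])
  if (any(dup)) {
    abort_parse(sprintf(
      "Duplicate (subject, age) pair at line %d.", which(dup)[1L] + line_offset
    ))
  }
  invisible(cohort)
}

#' Draw a population of individuals from a scenario
#'
#' Samples `n` individuals: baselines from `N(baseline_mean, baseline_sd^2)`
#' truncated below at 0 (at `convergence_floor` for S4) by rejection sampling,
#' and — for S3 — personal decline slopes from the zero-truncated normal
#' `(slope_mean, slope_sd)` via the inverse-CDF. Output is deterministic given
#' `(spec, n, seed)`; subject identifiers are `"s0001"`, `"s0002"`, ... in
#' draw order.
#'
#' @param spec A [scenario_spec()].
#' @param n Number of individuals (>= 1).
#' @param seed Integer seed.
#' @return A tibble with columns `subject_id`, `baseline`, and `slope`
#'   (individual decline rate for S3; `NA` otherwise).
#' @examples
#' draw_individuals(scenario_spec("S3"), n = 5, seed = 42)
#' @export
draw_individuals <- function(spec, n, seed) {
  validate_scenario_spec(spec)
  stopifnot(is_number(n), n >= 1)
  n <- as.integer(n)
  sid <- short_scenario(spec$scenario_id)
  lower <- if (sid == "S4") max(0, spec$convergence_floor) else 0

  seeds <- substream_seeds(seed, 4L)
  baseline <- with_seed(seeds[1L], rtrunc_normal_rejection(
    n, spec$baseline_mean, spec$baseline_sd, lower
  ))
  slope <- rep(NA_real_, n)
  if (sid == "S3") {
    slope <- with_seed(seeds[2L], rtrunc_normal_icdf(
      n, spec$slope_mean, spec$slope_sd, 0
    ))
  }
  tibble::tibble(
    subject_id = sprintf("s%04d", seq_len(n)),
    baseline = baseline,
    slope = slope
  )
}

## Truncated-normal sampling below at `lower` by vectorised rejection.
rtrunc_normal_rejection <- function(n, mean, sd, lower) {
  if (sd == 0) {
    if (mean <= lower) {
      abort_config(sprintf(
        "Zero baseline_sd with baseline_mean %g at or below the lower bound %g.",
        mean, lower
      ))
    }
    return(rep(mean, n))
  }
  accept_p <- pnorm(lower, mean, sd, lower.tail = FALSE)
  if (accept_p < 0.01) {
    abort_config(sprintf(
      "Degenerate truncation: rejection rate %.1f%% exceeds 99%%.",
      100 * (1 - accept_p)
    ))
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(ceiling((n - length(out)) / accept_p) + 10L, mean, sd)
    out <- c(out, draw[draw > lower])
  }
  out[seq_len(n)]
}

## Zero-truncated normal via inverse CDF (exact, no rejection loop).
rtrunc_normal_icdf <- function(n, mean, sd, lower) {
  if (sd == 0) {
    if (mean < lower) abort_config("Slope distribution entirely below its truncation point.")
    return(rep(mean, n))
  }
  p_lo <- pnorm(lower, mean, sd)
  qnorm(p_lo + runif(n) * (1 - p_lo), mean, sd)
}

#' Simulate a cross-sectional cohort
#'
#' Each of `n` subjects is observed once, at an age drawn uniformly on
#' `[baseline_age, max_age]`; the observed value is the noise-free trajectory
#' value plus `N(0, noise_sd^2)` measurement noise. Sub-streams for baselines,
#' slopes, ages and noise are derived from the one master seed, so the same
#' `(spec, n, seed)` always yields the same cohort and changing `noise_sd`
#' does not perturb the underlying individuals.
#'
#' @param spec A [scenario_spec()].
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed.
#' @return A `cohort_sample` tibble (`subject_id`, `age`, `value`) with
#'   design `"cross_sectional"`.
#' @examples
#' simulate_cross_sectional(scenario_spec("S2"), n = 5, seed = 1)
#' @export
simulate_cross_sectional <- function(spec, n, seed) {
  validate_scenario_spec(spec)
  stopifnot(is_number(n), n >= 1)
  n <- as.integer(n)
  seeds <- substream_seeds(seed, 4L)
  people <- draw_individuals(spec, n, seed)
  age <- with_seed(seeds[3L], runif(n, spec$baseline_age, spec$max_age))
  value <- trajectory_value(spec, people$baseline, age,
                            slope = people$slope, subject = people$subject_id)
  if (spec$noise_sd > 0) {
    value <- value + with_seed(seeds[4L], rnorm(n, 0, spec$noise_sd))
  }
  new_cohort(
    tibble::tibble(subject_id = people$subject_id, age = age, value = value),
    design = "cross_sectional",
    provenance = sprintf("simulated %s, n=%d, seed=%d", spec$scenario_id, n, seed)
  )
}

#' Simulate a longitudinal cohort
#'
#' Every subject is observed at every listed age, with fresh independent
#' measurement noise per observation — the ground-truth design that
#' cross-sectional dispersion analysis substitutes for.
#'
#' @param spec A [scenario_spec()].
#' @param n Number of subjects (>= 1).
#' @param ages At least two strictly increasing ages within
#'   `[baseline_age, max_age]`.
#' @param seed Integer seed.
#' @return A `cohort_sample` tibble with design `"longitudinal"`.
#' @export
simulate_longitudinal <- function(spec, n, ages, seed) {
  validate_scenario_spec(spec)
  stopifnot(is_number(n), n >= 1)
  if (length(ages) < 2L || any(diff(ages) <= 0)) {
    abort_contract("`ages` must contain at least 2 strictly increasing values.")
  }
  n <- as.integer(n)
  seeds <- substream_seeds(seed, 4L)
  people <- draw_individuals(spec, n, seed)
  grid <- tidyr::expand_grid(
    subject_id = people$subject_id,
    age = as.numeric(ages)
  )
  grid <- dplyr::left_join(grid, people, by = "subject_id")
  value <- trajectory_value(spec, grid$baseline, grid$age,
                            slope = grid$slope, subject = grid$subject_id)
  if (spec$noise_sd > 0) {
    value <- value + with_seed(seeds[4L], rnorm(nrow(grid), 0, spec$noise_sd))
  }
  new_cohort(
    tibble::tibble(subject_id = grid$subject_id, age = grid$age, value = value),
    design = "longitudinal",
    provenance = sprintf(
      "simulated %s longitudinal, n=%d, %d ages, seed=%d",
      spec$scenario_id, n, length(ages), seed
    )
  )
}

#' The three-exemplar illustration cohort
#'
#' A noise-free longitudinal cohort of three hypothetical individuals ranked
#' best / intermediate / worst at age 30 (baselines 100, 80 and 60 function
#' units) and followed yearly to age 80 under the requested scenario's default
#' rates. For S3 the three exemplars take fixed slopes 1.6, 0.8 and 0.1
#' units/year — a rapid, a modest and barely any decline. Under S1 the
#' best-ranked exemplar declines from 100 to exactly 50 (half the original
#' function left at 80).
#'
#' @param scenario Scenario identifier (as in [scenario_spec()]).
#' @return A `cohort_sample` with 3 subjects and 51 yearly observations each.
#' @examples
#' ex <- exemplar_cohort("S4")
#' dplyr::filter(ex, age == 80)
#' @export
exemplar_cohort <- function(scenario) {
  spec <- scenario_spec(scenario, noise_sd = 0)
  baselines <- c(100, 80, 60)
  slopes <- c(1.6, 0.8, 0.1)
  ages <- seq(spec$baseline_age, spec$max_age, by = 1)
  grid <- tidyr::expand_grid(subject = 1:3, age = ages)
  value <- trajectory_value(
    spec,
    baseline = baselines[grid$subject],
    age = grid$age,
    slope = slopes[grid$subject],
    subject = grid$subject
  )
  new_cohort(
    tibble::tibble(
      subject_id = sprintf("s%04d", grid$subject),
      age = as.numeric(grid$age),
      value = value
    ),
    design = "longitudinal",
    provenance = sprintf("three-exemplar illustration, %s", spec$scenario_id)
  )
}
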