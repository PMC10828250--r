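## Age-binned dispersion curves: per-bin n, mean, SD and COVAR.

#' Default equal-width age bin edges
#'
#' Equal-width edges covering `[t0, t_max]`; when the span is not an exact
#' multiple of `width`, the final bin absorbs the remainder (it is widened,
#' never dropped), so every age up to `t_max` falls in a bin. At least three
#' bins are required — the downstream trend fit needs three points.
#'
#' @param t0,t_max Age range (years), `t_max > t0`.
#' @param width Bin width in years (> 0). Default 10.
#' @return Numeric vector of bin edges.
#' @examples
#' age_bin_edges(30, 80)        # 30 40 50 60 70 80
#' age_bin_edges(30, 75, 10)    # 30 40 50 60 75 (last bin widened)
#' @export
age_bin_edges <- function(t0, t_max, width = 10) {
  stopifnot(is_number(t0), is_number(t_max), is_number(width), width > 0)
  if (t_max <= t0) abort_config("t_max must be greater than t0.")
  n_bins <- floor((t_max - t0) / width + 1e-9)
  if (n_bins < 3L) {
    abort_config(sprintf(
      "Width %g over [%g, %g] yields only %d bin(s); at least 3 bins are required.",
      width, t0, t_max, n_bins
    ))
  }
  edges <- t0 + width * (0:n_bins)
  if (edges[n_bins + 1L] < t_max) edges[n_bins + 1L] <- t_max
  edges
}

#' Bin a cross-sectional cohort into an age-resolved dispersion curve
#'
#' Groups a cross-sectional cohort into half-open age bins `[lo, hi)` (the
#' final bin is closed at its upper edge, so the oldest subjects are not
#' dropped) and computes, per bin: the number of subjects, the mean, the
#' sample SD (denominator n - 1) and the coefficient of variation
#' COVAR = 100 * SD / mean, in percent. These are the age-resolved absolute
#' and relative dispersion measures whose trends the framework classifies.
#'
#' @param cohort A cross-sectional `cohort_sample`. Longitudinal input is
#'   rejected: repeated measures would violate the independence the per-bin
#'   statistics assume.
#' @param edges Strictly increasing bin edges (at least 4, i.e. 3 bins),
#'   e.g. from [age_bin_edges()]. All observations must fall within them.
#' @param min_n Minimum subjects per bin (default 10); bins thinner than this
#'   give unreliable dispersion estimates and raise an error.
#' @return A `dispersion_curve`: a tibble with columns `bin_lo`, `bin_hi`,
#'   `midpoint`, `n`, `mean`, `sd`, `covar`, ordered by midpoint, carrying a
#'   `source` attribute with the cohort provenance.
#' @examples
#' co <- simulate_cross_sectional(scenario_spec("S2"), n = 500, seed = 9)
#' bin_cohort(co, age_bin_edges(30, 80))
#' @export
bin_cohort <- function(cohort, edges, min_n = 10) {
  validate_cohort(cohort)
  if (identical(cohort_design(cohort), "longitudinal")) {
    abort_contract(
      "Cohort is longitudinal; dispersion binning requires one observation per subject (cross-sectional design)."
    )
  }
  if (length(edges) < 4L || any(diff(edges) <= 0)) {
    abort_config("`edges` must be strictly increasing with at least 4 values (3 bins).")
  }
  out_of_range <- cohort$age < edges[1L] | cohort$age > edges[length(edges)]
  if (any(out_of_range)) {
    abort_range(sprintf(
      "%d observation(s) fall outside the binning range [%g, %g].",
      sum(out_of_range), edges[1L], edges[length(edges)]
    ))
  }
  # half-open [lo, hi); findInterval with the final edge folded into the last bin
  idx <- findInterval(cohort$age, edges, rightmost.closed = TRUE)
  n_bins <- length(edges) - 1L

  curve <- tibble::tibble(
    bin = seq_len(n_bins),
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1L]
  )
  stats <- tibble::tibble(bin = idx, value = cohort$value) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      .groups = "drop"
    )
  curve <- dplyr::left_join(curve, stats, by = "bin")
  curve$n[is.na(curve$n)] <- 0L

  thin <- curve$n < min_n
  if (any(thin)) {
    abort_config(sprintf(
      "Underpopulated bin(s) %s: fewer than min_n = %d subjects.",
      paste(sprintf("[%g,%g)", curve$bin_lo[thin], curve$bin_hi[thin]), collapse = ", "),
      as.integer(min_n)
    ))
  }
  if (any(curve$mean <= 0)) {
    bad <- which(curve$mean <= 0)[1L]
    abort_domain(sprintf(
      "Bin [%g,%g) has non-positive mean; COVAR undefined.",
      curve$bin_lo[bad], curve$bin_hi[bad]
    ))
  }
  curve <- curve |>
    dplyr::mutate(
      midpoint = (.data$bin_lo + .data$bin_hi) / 2,
      covar = 100 * .data$sd / .data$mean
    ) |>
    dplyr::select("bin_lo", "bin_hi", "midpoint", "n", "mean", "sd", "covar")
  structure(
    curve,
    class = c("dispersion_curve", class(curve)),
    source = cohort_provenance(cohort)
  )
}

#' @export
print.dispersion_curve <- function(x, ...) {
  cat(sprintf("<dispersion_curve> %d bins, source: %s\n",
              nrow(x), attr(x, "source") %||% "unknown"))
  NextMethod()
}
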