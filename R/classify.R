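## Map (SD direction, COVAR direction) to a scenario label and the coarse
## uniform / individualistic verdict.

## Signature texts attached to the verdict rationale.
.signature_text <- c(
  S1_uniform_relative = "SD decreases with age while COVAR is constant: everyone loses the same fraction of their own baseline (uniform relative decline).",
  S2_uniform_absolute = "SD stays constant while COVAR increases with age: everyone loses the same absolute amount (uniform absolute, individualistic in relative terms).",
  S3_random_individual = "Both SD and COVAR increase with age: individual decline rates vary at random (highly individualistic).",
  S4_convergent = "Both SD and COVAR decrease with age: the highest starting values lose the most, trajectories converge (highly individualistic).",
  indeterminate = "The (SD, COVAR) direction pair matches none of the four modelled decline scenarios."
)

fine_label_of <- function(sd_dir, covar_dir) {
  key <- paste(sd_dir, covar_dir, sep = "/")
  switch(key,
    "decrease/none" = "S1_uniform_relative",
    "none/increase" = "S2_uniform_absolute",
    "increase/increase" = "S3_random_individual",
    "decrease/decrease" = "S4_convergent",
    "indeterminate"
  )
}

coarse_label_of <- function(sd_dir, covar_dir) {
  if (covar_dir %in% c("increase", "decrease")) {
    "individualistic"
  } else if (sd_dir %in% c("decrease", "none")) {
    # flat COVAR with non-increasing SD: relative spread preserved
    "uniform"
  } else {
    # rising absolute spread with flat relative spread matches no scenario
    "indeterminate"
  }
}

new_framework_verdict <- function(sd_trend, covar_trend, provenance = NULL,
                                  binning = NULL) {
  sd_dir <- sd_trend$direction
  covar_dir <- covar_trend$direction
  fine <- fine_label_of(sd_dir, covar_dir)
  coarse <- coarse_label_of(sd_dir, covar_dir)
  rationale <- .signature_text[[fine]]
  if (sd_dir == "none" && covar_dir == "none") {
    rationale <- paste(
      "Neither SD nor COVAR shows a significant age trend; the relative spread is preserved (uniform),",
      "but a flat pair may simply reflect an underpowered study or the absence of any decline."
    )
  }
  structure(
    list(
      sd_direction = sd_dir,
      covar_direction = covar_dir,
      fine_label = fine,
      coarse_label = coarse,
      rationale = rationale,
      evidence = list(SD = sd_trend, COVAR = covar_trend),
      provenance = provenance,
      binning = binning
    ),
    class = "framework_verdict"
  )
}

#' Classify a population from its SD and COVAR age trends
#'
#' The core decision rule: the pair of direction calls for the age trend of
#' the standard deviation and of the coefficient of variation is mapped to the
#' generative scenario whose signature it matches, and to a coarse verdict on
#' the rate of ageing.
#'
#' Fine mapping: (SD decrease, COVAR none) -> S1 uniform relative;
#' (none, increase) -> S2 uniform absolute; (increase, increase) -> S3 random
#' individual; (decrease, decrease) -> S4 convergent; every other pair is
#' indeterminate.
#'
#' Coarse mapping: a flat COVAR with non-increasing SD means the relative
#' spread of the population is preserved — a 'uniform' rate of ageing. Any
#' significant change in COVAR, up or down, means relative spread changes —
#' a 'highly individualistic' rate. A rising SD with flat COVAR matches no
#' modelled scenario and stays indeterminate.
#'
#' @param sd_trend A `trend_result` for statistic `"SD"`.
#' @param covar_trend A `trend_result` for statistic `"COVAR"`.
#' @return A `framework_verdict` with fields `sd_direction`,
#'   `covar_direction`, `fine_label`, `coarse_label`, `rationale` and the two
#'   trends under `evidence`.
#' @examples
#' co <- simulate_cross_sectional(scenario_spec("S2"), n = 2000, seed = 5)
#' curve <- bin_cohort(co, age_bin_edges(30, 80))
#' classify(wls_trend(curve, "SD"), wls_trend(curve, "COVAR"))
#' @export
classify <- function(sd_trend, covar_trend) {
  if (!inherits(sd_trend, "trend_result") || !inherits(covar_trend, "trend_result")) {
    abort_contract("`sd_trend` and `covar_trend` must be trend_result objects.")
  }
  if (!identical(sd_trend$statistic, "SD") || !identical(covar_trend$statistic, "COVAR")) {
    abort_contract(sprintf(
      "Expected one SD and one COVAR trend, got (%s, %s); statistics swapped or duplicated.",
      sd_trend$statistic, covar_trend$statistic
    ))
  }
  new_framework_verdict(sd_trend, covar_trend)
}

#' Analyse a cross-sectional cohort end to end
#'
#' Composition of the whole framework: bin the cohort into age groups
#' ([bin_cohort()]), fit the age trend of SD and of COVAR by the chosen
#' method ([wls_trend()] or [bootstrap_trend()]), and map the pair of
#' direction calls to a verdict ([classify()]). With the bootstrap, both
#' statistics are assessed on the same seeded resamples. No multiplicity
#' correction is applied across the two trends: the framework interprets the
#' pair jointly as a single decision.
#'
#' @param cohort A cross-sectional `cohort_sample`.
#' @param edges Bin edges; defaults to 10-year bins over the cohort's age
#'   range via [age_bin_edges()].
#' @param method `"wls"` (weighted least squares with asymptotic standard
#'   errors) or `"bootstrap"` (stratified within-bin resampling; recommended
#'   for real data).
#' @param alpha Two-sided significance level. Default 0.05.
#' @param n_boot Bootstrap replicates (bootstrap method only). Default 2000.
#' @param seed Integer seed (bootstrap method only). Default 1.
#' @param min_n Minimum subjects per bin. Default 10.
#' @return A `framework_verdict`; the fitted trends are kept in
#'   `$evidence`.
#' @examples
#' co <- simulate_cross_sectional(scenario_spec("S3"), n = 3000, seed = 7)
#' analyze_cohort(co, method = "wls")
#' @export
analyze_cohort <- function(cohort, edges = NULL, method = c("wls", "bootstrap"),
                           alpha = 0.05, n_boot = 2000, seed = 1, min_n = 10) {
  method <- match.arg(method)
  validate_cohort(cohort)
  if (is.null(edges)) {
    edges <- age_bin_edges(floor(min(cohort$age)), ceiling(max(cohort$age)))
  }
  if (method == "wls") {
    curve <- bin_cohort(cohort, edges, min_n = min_n)
    sd_trend <- wls_trend(curve, "SD", alpha = alpha)
    covar_trend <- wls_trend(curve, "COVAR", alpha = alpha)
  } else {
    sd_trend <- bootstrap_trend(cohort, "SD", edges, n_boot = n_boot,
                                alpha = alpha, seed = seed, min_n = min_n)
    covar_trend <- bootstrap_trend(cohort, "COVAR", edges, n_boot = n_boot,
                                   alpha = alpha, seed = seed, min_n = min_n)
  }
  verdict <- classify(sd_trend, covar_trend)
  verdict$provenance <- cohort_provenance(cohort)
  verdict$binning <- edges
  verdict
}

#' @export
print.framework_verdict <- function(x, ...) {
  cat(sprintf(
    "<framework_verdict> %s rate of ageing (%s)\n  SD: %s, COVAR: %s\n  %s\n",
    x$coarse_label, x$fine_label, x$sd_direction, x$covar_direction, x$rationale
  ))
  invisible(x)
}

#' Tidy a framework verdict
#'
#' `tidy()` returns one row per evidence trend (SD, COVAR); `glance()` returns
#' the one-row verdict summary.
#'
#' @param x A `framework_verdict`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.framework_verdict <- function(x, ...) {
  dplyr::bind_rows(tidy(x$evidence$SD), tidy(x$evidence$COVAR))
}

#' @rdname tidy.framework_verdict
#' @export
glance.framework_verdict <- function(x, ...) {
  tibble::tibble(
    sd_direction = x$sd_direction,
    covar_direction = x$covar_direction,
    fine_label = x$fine_label,
    coarse_label = x$coarse_label,
    method = x$evidence$SD$method
  )
}

#' Serialise a verdict to a JSON report list
#'
#' Plain-list form of a `framework_verdict` (provenance, binning, the two
#' trend blocks, labels and rationale) suitable for
#' `jsonlite::write_json(..., auto_unbox = TRUE)`.
#'
#' @param verdict A `framework_verdict`.
#' @param config Optional named list echoed into the report (reproducibility
#'   contract of the command-line interface).
#' @return A named list.
#' @export
verdict_report <- function(verdict, config = NULL) {
  trend_block <- function(tr) {
    list(
      statistic = tr$statistic, slope = tr$slope,
      ci_low = tr$ci_low, ci_high = tr$ci_high,
      alpha = tr$alpha, method = tr$method,
      n_boot = if (is.na(tr$n_boot)) NULL else tr$n_boot,
      seed = if (is.na(tr$seed)) NULL else tr$seed,
      direction = tr$direction
    )
  }
  list(
    provenance = verdict$provenance,
    binning = verdict$binning,
    trends = list(
      SD = trend_block(verdict$evidence$SD),
      COVAR = trend_block(verdict$evidence$COVAR)
    ),
    fine_label = verdict$fine_label,
    coarse_label = verdict$coarse_label,
    rationale = verdict$rationale,
    software_version = as.character(packageVersion("agecovar")),
    config = config
  )
}
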