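## ggplot2 views of cohorts, dispersion curves and scenario moment curves.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cohort sample
#'
#' Cross-sectional cohorts are drawn as an age-value scatter; longitudinal
#' cohorts as one line per subject (the classic decline-trajectory view).
#'
#' @param object A `cohort_sample`.
#' @param alpha Point/line transparency.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(exemplar_cohort("S4"))
#' @export
autoplot.cohort_sample <- function(object, alpha = 0.6, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$value))
  if (identical(cohort_design(object), "longitudinal")) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(group = .data$subject_id, colour = .data$subject_id),
      alpha = alpha, show.legend = length(unique(object$subject_id)) <= 10
    )
  } else {
    p <- p + ggplot2::geom_point(alpha = alpha, size = 0.8)
  }
  p +
    ggplot2::labs(
      x = "Age (years)", y = "Physiological function",
      title = cohort_provenance(object)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a dispersion curve
#'
#' The per-bin SD (red) and COVAR (blue) against bin midpoint — the two
#' dispersion summaries whose joint age trend the framework classifies. The
#' two statistics live on different scales, so each is drawn in its own facet.
#'
#' @param object A `dispersion_curve` from [bin_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dispersion_curve <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("sd", "covar"), names_to = "statistic", values_to = "value") |>
    dplyr::mutate(statistic = dplyr::recode(.data$statistic,
      sd = "SD (function units)", covar = "COVAR (%)"
    ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$midpoint, y = .data$value,
                                     colour = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::scale_colour_manual(
      values = c("SD (function units)" = "#c0392b", "COVAR (%)" = "#2c5f9e"),
      guide = "none"
    ) +
    ggplot2::labs(x = "Age-bin midpoint (years)", y = NULL,
                  title = attr(object, "source") %||% "dispersion curve") +
    ggplot2::theme_minimal()
}

#' Plot the theoretical moment curves of a scenario
#'
#' Mean, SD and COVAR of the noise-free population over the modelled age
#' range, from [analytic_moments()].
#'
#' @param spec A [scenario_spec()].
#' @param by Age step for the curve grid (years). Default 1.
#' @return A ggplot object.
#' @examples
#' plot_scenario_moments(scenario_spec("S4"))
#' @export
plot_scenario_moments <- function(spec, by = 1) {
  ages <- seq(spec$baseline_age, spec$max_age, by = by)
  long <- moment_trajectory(spec, ages) |>
    tidyr::pivot_longer(c("mean", "sd", "covar"),
                        names_to = "moment", values_to = "value") |>
    dplyr::mutate(moment = factor(.data$moment, levels = c("mean", "sd", "covar"),
                                  labels = c("Mean", "SD", "COVAR (%)")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c5f9e") +
    ggplot2::facet_wrap(~moment, scales = "free_y") +
    ggplot2::labs(x = "Age (years)", y = NULL, title = spec$scenario_id) +
    ggplot2::theme_minimal()
}
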