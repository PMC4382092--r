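#' Plot success proportions with Wilson intervals
#'
#' Bar-style summary of the per-cell success proportions by genotype and
#' treatment, with Wilson confidence intervals as error bars.
#'
#' @param table outcome table.
#' @param level confidence level.
#' @param continuity continuity correction for the intervals.
#' @return a ggplot object.
#' @export
plot_success_proportions <- function(table, level = 0.95,
                                     continuity = TRUE) {
  props <- outcome_proportions(table, level = level,
                               continuity = continuity) |>
    dplyr::filter(.data$measure == "success") |>
    dplyr::mutate(
      genotype = factor(.data$genotype, levels = GENOTYPES),
      treatment = factor(.data$treatment, levels = TREATMENTS)
    )
  ggplot2::ggplot(props,
                  ggplot2::aes(x = .data$genotype, y = .data$p_hat)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30", width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      width = 0.2) +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Kdr genotype", y = "proportion successful") +
    ggplot2::theme_minimal()
}

#' @describeIn mc_profile Cloud-and-envelope plot of a Monte-Carlo profile.
#'   Shows the attained log-likelihood of each draw against the implied
#'   parameter value, the binned upper envelope, and the likelihood-ratio
#'   threshold.
#' @param object a `kdr_profile`.
#' @param parameter `"s"` or `"h"`.
#' @param level confidence level for the threshold line.
#' @param max_points subsample size for the plotted cloud.
#' @param ... ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.kdr_profile <- function(object, parameter = c("s", "h"),
                                 level = 0.95, max_points = 20000, ...) {
  parameter <- match.arg(parameter)
  env <- if (parameter == "s") object$envelope_s else object$envelope_h
  rng <- if (parameter == "s") object$s_range else object$h_range
  thr <- object$max_ll - qchisq(level, 1) / 2
  gg <- ggplot2::ggplot()
  if (!is.null(object$draws)) {
    draws <- object$draws[is.finite(object$draws[[parameter]]) &
                            object$draws[[parameter]] >= rng[1] &
                            object$draws[[parameter]] <= rng[2], ]
    if (nrow(draws) > max_points) {
      draws <- draws[seq.int(1, nrow(draws),
                             length.out = max_points), ]
    }
    gg <- gg + ggplot2::geom_point(
      data = draws,
      ggplot2::aes(x = .data[[parameter]], y = .data$log_lik),
      alpha = 0.08, size = 0.3, colour = "steelblue")
  }
  gg +
    ggplot2::geom_step(
      data = env[!is.na(env$max_ll), ],
      ggplot2::aes(x = .data$mid, y = .data$max_ll),
      colour = "black") +
    ggplot2::geom_hline(yintercept = thr, linetype = 2,
                        colour = "firebrick") +
    ggplot2::coord_cartesian(
      ylim = c(object$max_ll - 4 * qchisq(level, 1), object$max_ll + 0.5)) +
    ggplot2::labs(
      x = parameter, y = "profile log-likelihood",
      title = paste0("Monte-Carlo profile likelihood (",
                     object$treatment, ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
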