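#' Poincare plot of an NN series
#'
#' Scatter of each NN interval against its successor, with the identity line;
#' the cloud's spread across and along that line corresponds to SD1 and SD2.
#'
#' @param nn Numeric vector of NN intervals (ms).
#' @return A ggplot object.
#' @export
plot_poincare <- function(nn) {
  stopifnot(length(nn) >= 3)
  d <- tibble(nn_i = nn[-length(nn)], nn_next = nn[-1])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$nn_i, y = .data$nn_next)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "NN(i) [ms]", y = "NN(i+1) [ms]", title = "Poincare plot")
}

#' Plot an HRV age-dependency fit
#'
#' @param object An `hrv_depfit` from [fit_dependency()].
#' @param ... Unused.
#' @return A ggplot object: the per-subject points and the fitted line.
#' @export
autoplot.hrv_depfit <- function(object, ...) {
  d <- tibble(age = object$fit$model$x, value = object$fit$model$y)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "age [years]", y = "HRV parameter [ms]",
      title = sprintf("y = %.2f %+.3f * age (r = %.2f)",
                      object$intercept, object$slope, object$r)
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot quartile normal ranges by age group
#'
#' Ribbon/point display of per-group Q1-Q3 ranges and medians from
#' [group_quartiles()], faceted by gender.
#'
#' @param ranges Output of [group_quartiles()].
#' @return A ggplot object.
#' @export
plot_quartile_ranges <- function(ranges) {
  ggplot2::ggplot(ranges, ggplot2::aes(x = .data$age_group, group = .data$gender)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                            linewidth = 2, alpha = 0.4, colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$q2), size = 2) +
    ggplot2::facet_wrap(~gender) +
    ggplot2::labs(x = "age group", y = "HRV parameter [ms]",
                  title = unique(ranges$parameter))
}
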