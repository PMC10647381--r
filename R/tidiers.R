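#' Tidy an HRV age-dependency fit
#'
#' @param x An `hrv_depfit` from [fit_dependency()].
#' @param ... Unused.
#' @return A tibble with one row per model term (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`), terms named `(Intercept)` and
#'   `age`.
#' @export
tidy.hrv_depfit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("(Intercept)", "age"),
    estimate = unname(s[, 1]),
    std.error = unname(s[, 2]),
    statistic = unname(s[, 3]),
    p.value = unname(s[, 4])
  )
}

#' Glance at an HRV age-dependency fit
#'
#' @inheritParams tidy.hrv_depfit
#' @return A one-row tibble: `r`, `r.squared`, `p.value`, `sigma`, `nobs`,
#'   `intercept`, `slope`.
#' @export
glance.hrv_depfit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r = x$r, r.squared = s$r.squared, p.value = x$p, sigma = s$sigma,
         nobs = x$n, intercept = x$intercept, slope = x$slope)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
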