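#' Correlation tests
#'
#' `cor_pearson()` is the product-moment correlation with a two-sided p-value
#' from the t transform on n - 2 degrees of freedom. `cor_spearman()` is the
#' Pearson correlation of the mid-ranks (average ranks on ties), with the
#' p-value from the same t transform applied to the rank correlation.
#' `cor_point_biserial()` correlates a dichotomous variable with a continuous
#' one; it equals the Pearson correlation on a 0/1 coding. Gender is coded
#' M = 0, F = 1 throughout the package, so a negative coefficient means lower
#' values in females.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, both nonconstant.
#' @param binary A vector of 0/1 (or `"M"`/`"F"`, coded 0/1); both groups must
#'   be non-empty.
#' @return A one-row tibble with `method`, `r`, `p`, `n`.
#' @name correlations
NULL

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("correlation undefined for constant input")
}

#' @rdname correlations
#' @export
cor_pearson <- function(x, y) {
  check_cor_input(x, y)
  ct <- cor.test(x, y, method = "pearson")
  tibble(method = "pearson", r = unname(ct$estimate), p = ct$p.value,
         n = length(x))
}

#' @rdname correlations
#' @export
cor_spearman <- function(x, y) {
  check_cor_input(x, y)
  ct <- cor.test(rank(x), rank(y), method = "pearson")
  tibble(method = "spearman", r = unname(ct$estimate), p = ct$p.value,
         n = length(x))
}

#' @rdname correlations
#' @export
cor_point_biserial <- function(binary, y) {
  b <- code_binary(binary)
  if (length(unique(b)) < 2) stop("both groups must be non-empty")
  out <- cor_pearson(b, y)
  out$method <- "point_biserial"
  out
}

code_binary <- function(binary) {
  if (is.character(binary) || is.factor(binary)) {
    b <- as.character(binary)
    if (!all(b %in% c("M", "F"))) stop("character binary variable must be M/F")
    as.numeric(b == "F")
  } else {
    if (!all(binary %in% c(0, 1))) stop("numeric binary variable must be 0/1")
    as.numeric(binary)
  }
}

#' Two-group location and distribution tests
#'
#' Runs the three two-sample tests used for the male/female and
#' healthy/arrhythmia comparisons: Welch's t-test (unequal variances,
#' Welch-Satterthwaite degrees of freedom), the Mann-Whitney U test (normal
#' approximation with tie and continuity corrections) and the two-sample
#' Kolmogorov-Smirnov test (asymptotic p). All p-values are two-sided and
#' reported raw, with group sizes.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A tibble with one row per test: `test`, `statistic`, `p`, `n_a`,
#'   `n_b`.
#' @export
two_group_tests <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs at least 2 values")
  tt <- t.test(a, b, var.equal = FALSE)
  wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  n_a <- length(a); n_b <- length(b)
  ks_p <- kolmogorov_sf(sqrt(n_a * n_b / (n_a + n_b)) * unname(kt$statistic))
  tibble(
    test = c("welch_t", "mann_whitney_u", "ks"),
    statistic = c(unname(tt$statistic), unname(wt$statistic), unname(kt$statistic)),
    p = c(tt$p.value, wt$p.value, ks_p),
    n_a = n_a, n_b = n_b
  )
}

# Survival function of the Kolmogorov distribution,
# Q(lambda) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2),
# summed to full floating-point precision (the alternating series terminates
# quickly for any lambda the two-sample statistic can produce).
kolmogorov_sf <- function(lambda) {
  if (lambda < 1e-3) return(1)
  total <- 0
  for (k in 1:200) {
    term <- (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
    total <- total + term
    if (abs(term) < 1e-17) break
  }
  min(1, max(0, 2 * total))
}

#' Fit a linear age dependency function
#'
#' Ordinary least squares fit of an HRV parameter on age, `y = intercept +
#' slope * age`, the form used to summarise how HRV declines with age in
#' healthy and arrhythmia groups. The correlation `r` and its p-value are the
#' Pearson ones.
#'
#' @param data A data frame of per-subject values.
#' @param value Column holding the HRV parameter (tidy-eval).
#' @param age Column holding age in years (tidy-eval, default `age`).
#' @return An object of class `hrv_depfit`; see [tidy.hrv_depfit()] and
#'   [glance.hrv_depfit()]. Key fields: `intercept` (ms), `slope` (ms/year),
#'   `r`, `p`, `n`, and the underlying `lm` fit.
#' @examples
#' d <- tibble::tibble(age = 20:80, a_sdnn = 60.62 - 0.49 * (20:80))
#' fit_dependency(d, a_sdnn)
#' @export
fit_dependency <- function(data, value, age = age) {
  y <- dplyr::pull(data, {{ value }})
  x <- dplyr::pull(data, {{ age }})
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (sd(x) == 0) stop("ages are constant; dependency undefined")
  fit <- lm(y ~ x)
  ct <- if (sd(y) > 0) cor.test(x, y) else NULL
  structure(
    list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
         r = if (is.null(ct)) NA_real_ else unname(ct$estimate),
         p = if (is.null(ct)) NA_real_ else ct$p.value,
         n = length(x), fit = fit),
    class = "hrv_depfit"
  )
}

#' @export
print.hrv_depfit <- function(x, ...) {
  cat(sprintf("HRV age dependency: y = %.4f %+.4f * age  (r = %.3f, p = %.3g, n = %d)\n",
              x$intercept, x$slope, x$r, x$p, x$n))
  invisible(x)
}

#' Age-group binning
#'
#' Assigns ages to the six study age groups with half-open bins: `<30` is
#' (0, 30), then [30, 40), [40, 50), [50, 60), [60, 70), and `>70` is
#' [70, 130) -- so a 70-year-old falls in `>70`.
#'
#' @param age Numeric vector of ages in years, each in (0, 130).
#' @return A factor with levels `<30`, `30-40`, `40-50`, `50-60`, `60-70`,
#'   `>70`.
#' @export
age_group <- function(age) {
  if (any(age <= 0 | age >= 130)) stop("age out of range (0, 130)")
  cut(age, breaks = c(0, 30, 40, 50, 60, 70, 130),
      labels = AGE_GROUP_LEVELS, right = FALSE)
}

AGE_GROUP_LEVELS <- c("<30", "30-40", "40-50", "50-60", "60-70", ">70")

#' Cohort correlation matrix
#'
#' Correlates each HRV parameter column against age and/or gender, optionally
#' within groups. Gender uses the point-biserial coefficient (M = 0, F = 1)
#' for the `"pearson"` method and Spearman on the coded variable otherwise.
#' Rows with a missing parameter value are dropped per cell; cells with fewer
#' than 3 complete rows are reported with `NA` and a reason.
#'
#' @param cohort A data frame with columns `age`, `gender` and the parameter
#'   columns (typically per-subject mean window HRV).
#' @param params Character vector of HRV parameter column names.
#' @param targets Subset of `c("age", "gender")`.
#' @param methods Subset of `c("pearson", "spearman")`.
#' @param by Optional grouping column name (e.g. `"condition"`).
#' @return A tidy tibble: one row per (group, target, parameter, method) with
#'   `r`, `p`, `n`, `reason`.
#' @export
correlation_matrix <- function(cohort, params, targets = c("age", "gender"),
                               methods = c("pearson", "spearman"), by = NULL) {
  targets <- match.arg(targets, several.ok = TRUE)
  methods <- match.arg(methods, several.ok = TRUE)
  groups <- if (is.null(by)) list(`all` = cohort) else split(cohort, cohort[[by]])
  cells <- list()
  for (g in names(groups)) {
    dat <- groups[[g]]
    for (target in targets) {
      tv <- if (target == "gender") code_binary(dat$gender) else dat$age
      for (param in params) {
        yv <- dat[[param]]
        ok <- complete.cases(tv, yv)
        for (method in methods) {
          row <- if (sum(ok) < 3) {
            tibble(method = method, r = NA_real_, p = NA_real_, n = sum(ok))
          } else {
            fn <- if (method == "pearson") cor_pearson else cor_spearman
            res <- tryCatch(fn(tv[ok], yv[ok]), error = function(e) NULL)
            if (is.null(res)) {
              tibble(method = method, r = NA_real_, p = NA_real_, n = sum(ok))
            } else {
              res$method <- method
              res
            }
          }
          if (target == "gender" && method == "pearson") {
            row$method <- "point_biserial"
          }
          row$reason <- if (is.na(row$r)) "insufficient n or constant input" else NA_character_
          cells[[length(cells) + 1L]] <- dplyr::bind_cols(
            tibble(group = g, target = target, parameter = param), row
          )
        }
      }
    }
  }
  dplyr::bind_rows(cells)
}
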