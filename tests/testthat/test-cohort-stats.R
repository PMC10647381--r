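test_that("correlation fixtures and textbook-oracle equivalence hold", {
  expect_equal(cor_pearson(c(1, 2, 3), c(2, 4, 6))$r, 1, tolerance = 1e-12)
  expect_equal(cor_pearson(c(1, 2, 3), c(3, 2, 1))$r, -1, tolerance = 1e-12)
  expect_equal(cor_pearson(c(0, 0, 1, 1), c(1, 2, 3, 4))$r, 2 / sqrt(5),
               tolerance = 1e-9) # 0.8944
  x <- 1:5
  expect_equal(cor_spearman(x, x^3)$r, 1, tolerance = 1e-12)
  expect_equal(cor_spearman(x, -x)$r, -1, tolerance = 1e-12)
  expect_equal(cor_spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8,
               tolerance = 1e-12)

  set.seed(17)
  for (case in 1:60) {
    n <- sample(4:100, 1)
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    if (case %% 3 == 0) y <- round(y, 1) # ties for the rank path
    po <- oracle_pearson(x, y)
    pg <- cor_pearson(x, y)
    expect_equal(pg$r, po$r, tolerance = 1e-12)
    expect_equal(pg$p, po$p, tolerance = 1e-12)
    so <- oracle_spearman(x, y)
    sg <- cor_spearman(x, y)
    expect_equal(sg$r, so$r, tolerance = 1e-12)
    expect_equal(sg$p, so$p, tolerance = 1e-12)
  }
})

test_that("point-biserial equals pearson on the 0/1 coding", {
  expect_equal(cor_point_biserial(c(0, 0, 1, 1), c(1, 2, 3, 4))$r, 2 / sqrt(5),
               tolerance = 1e-9)
  expect_equal(cor_point_biserial(c("M", "M", "F", "F"), c(1, 2, 3, 4))$r,
               2 / sqrt(5), tolerance = 1e-9)
  set.seed(23)
  for (case in 1:30) {
    b <- rbinom(20, 1, 0.5)
    if (length(unique(b)) < 2) next
    y <- rnorm(20)
    expect_equal(cor_point_biserial(b, y)$r, cor_pearson(b, y)$r,
                 tolerance = 1e-14)
  }
  expect_error(cor_point_biserial(rep(1, 5), rnorm(5)), "non-empty")
  # no separation between the groups
  expect_equal(cor_point_biserial(c(0, 1, 0, 1), c(2, 2, 5, 5))$r, 0,
               tolerance = 1e-12)
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(29)
  for (case in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    base <- cor_spearman(x, y)$r
    expect_equal(cor_spearman(exp(x), y)$r, base, tolerance = 1e-12)
    expect_equal(cor_spearman(x, y^3)$r, base, tolerance = 1e-12)
  }
})

test_that("two-group tests match textbook oracles and fixtures", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  out <- two_group_tests(a, b)
  expect_equal(out$statistic[out$test == "mann_whitney_u"], 0)

  same <- two_group_tests(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic[same$test == "welch_t"], 0)
  expect_equal(same$statistic[same$test == "ks"], 0)

  set.seed(37)
  for (case in 1:40) {
    x <- rnorm(sample(5:60, 1)); y <- rnorm(sample(5:60, 1), 0.3)
    if (case %% 4 == 0) { x <- round(x, 1); y <- round(y, 1) } # ties
    got <- two_group_tests(x, y)
    ow <- oracle_welch(x, y); om <- oracle_mwu(x, y); ok <- oracle_ks(x, y)
    expect_equal(got$statistic[got$test == "welch_t"], ow$statistic, tolerance = 1e-12)
    expect_equal(got$p[got$test == "welch_t"], ow$p, tolerance = 1e-12)
    expect_equal(got$statistic[got$test == "mann_whitney_u"], om$statistic, tolerance = 1e-12)
    expect_equal(got$p[got$test == "mann_whitney_u"], om$p, tolerance = 1e-12)
    expect_equal(got$statistic[got$test == "ks"], ok$statistic, tolerance = 1e-12)
    expect_equal(got$p[got$test == "ks"], ok$p, tolerance = 1e-12)
  }
})

test_that("well-separated groups are detected by all three tests", {
  set.seed(41)
  a <- rnorm(200, 0, 1); b <- rnorm(200, 2, 1)
  out <- two_group_tests(a, b)
  expect_true(all(out$p < 0.01))
})

test_that("dependency fit recovers noiseless linear coefficients exactly", {
  ages <- 20:80
  f2 <- fit_dependency(tibble::tibble(age = ages, y = 60.62 - 0.49 * ages), y)
  expect_equal(f2$intercept, 60.62, tolerance = 1e-9)
  expect_equal(f2$slope, -0.49, tolerance = 1e-9)
  f4 <- fit_dependency(tibble::tibble(age = ages, y = 44.30 - 0.13 * ages), y)
  expect_equal(f4$intercept, 44.30, tolerance = 1e-9)
  expect_equal(f4$slope, -0.13, tolerance = 1e-9)

  flat <- fit_dependency(tibble::tibble(age = ages, y = rep(7, length(ages))), y)
  expect_equal(flat$intercept, 7, tolerance = 1e-12)
  expect_equal(flat$slope, 0, tolerance = 1e-12)

  expect_error(fit_dependency(tibble::tibble(age = rep(50, 5), y = rnorm(5)), y),
               "constant")
})

test_that("noisy slope estimates fall inside their 99% CI almost always", {
  set.seed(43)
  hits <- 0
  reps <- 500
  for (r in seq_len(reps)) {
    ages <- runif(200, 20, 80)
    y <- 60.62 - 0.49 * ages + rnorm(200, 0, 5)
    fit <- fit_dependency(tibble::tibble(age = ages, y = y), y)
    se <- tidy(fit)$std.error[2]
    crit <- qt(0.995, 198)
    hits <- hits + (abs(fit$slope - (-0.49)) <= crit * se)
  }
  expect_gte(hits / reps, 0.95)
})

test_that("tidy and glance expose the fit in broom form", {
  d <- tibble::tibble(age = runif(50, 20, 80))
  d$y <- 50 - 0.3 * d$age + rnorm(50, 0, 2)
  fit <- fit_dependency(d, y)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "age"))
  expect_equal(td$estimate, c(fit$intercept, fit$slope))
  gl <- glance(fit)
  expect_equal(gl$nobs, 50)
  expect_equal(gl$slope, fit$slope)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("age groups bin half-open with 70 in the oldest group", {
  expect_equal(as.character(age_group(c(35, 70, 29.9, 30, 69.99, 45))),
               c("30-40", ">70", "<30", "30-40", "60-70", "40-50"))
  expect_error(age_group(131), "out of range")
  expect_error(age_group(0), "out of range")
})

test_that("correlation matrix flags trends, perfect copies and undersized cells", {
  set.seed(47)
  n <- 120
  cohort <- tibble::tibble(
    age = runif(n, 20, 80),
    gender = sample(c("M", "F"), n, replace = TRUE)
  )
  cohort$a_sdnn <- 60.62 - 0.49 * cohort$age + rnorm(n, 0, 5)
  cohort$copy_age <- cohort$age
  out <- correlation_matrix(cohort, c("a_sdnn", "copy_age"))
  sdnn_age <- out[out$parameter == "a_sdnn" & out$target == "age", ]
  expect_true(all(sdnn_age$r < 0))
  copy_age <- out[out$parameter == "copy_age" & out$target == "age", ]
  expect_true(all(abs(copy_age$r - 1) < 1e-12))
  expect_true(all(out$method[out$target == "gender" &
                             out$method != "spearman"] == "point_biserial"))

  tiny <- cohort[1:2, ]
  out2 <- correlation_matrix(tiny, "a_sdnn")
  expect_true(all(is.na(out2$r)))
  expect_true(all(!is.na(out2$reason)))
})

test_that("gender coding makes a known female deficit come out negative", {
  set.seed(53)
  n <- 200
  gender <- sample(c("M", "F"), n, replace = TRUE)
  y <- 40 - 3 * (gender == "F") + rnorm(n, 0, 2)
  out <- cor_point_biserial(gender, y)
  expect_lt(out$r, 0)
  expect_lt(out$p, 0.01)
})
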