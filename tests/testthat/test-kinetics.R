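test_that("regress handles exact, degenerate and through-origin cases", {
  d <- tibble::tibble(x = c(50, 150, 278), y = 2e-4 * c(50, 150, 278))
  f <- regress(d, y, x)
  expect_equal(f$slope, 2e-4, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)

  dc <- tibble::tibble(x = 1:10, y = 5)
  fc <- regress(dc, y, x)
  expect_equal(fc$slope, 0, tolerance = 1e-12)
  expect_equal(fc$r_squared, 0)

  expect_error(regress(tibble::tibble(x = c(1, 1, 1), y = 1:3), y, x),
               "constant")
  expect_error(regress(d[1:2, ], y, x), "at least")
  f0 <- regress(d[1:2, ], y, x, through_origin = TRUE)
  expect_equal(f0$slope, 2e-4, tolerance = 1e-12)
  expect_true(is.na(f0$intercept))
})

test_that("regression coefficients match the normal-equations oracle", {
  set.seed(42)
  for (i in 1:5) {
    n <- sample(10:100, 1)
    d <- tibble::tibble(x = rnorm(n), y = rnorm(n))
    f <- regress(d, y, x)
    beta <- ols_oracle(d$x, d$y)
    expect_equal(f$intercept, beta[1], tolerance = 1e-10)
    expect_equal(f$slope, beta[2], tolerance = 1e-10)
    f0 <- regress(d, y, x, through_origin = TRUE)
    beta0 <- ols_oracle(d$x, d$y, intercept = FALSE)
    expect_equal(f0$slope, beta0[1], tolerance = 1e-10)
  }
})

test_that("decay rate recovers the constructed herbarium rate and ratio", {
  # lambda lying exactly on lambda = 1.66e-4 * age
  d <- tibble::tibble(age = c(50, 150, 278),
                      lambda_hat = 1.66e-4 * c(50, 150, 278))
  fit <- estimate_decay_rate(d)
  expect_equal(fit$k, 1.66e-4, tolerance = 1e-12)
  expect_equal(fit$through_origin$r_squared, 1)
  # the herbarium rate is about six times the published bone rate
  expect_identical(round(fit$k / 2.71e-5), 6)

  # flagged-lambda samples are excluded
  d2 <- dplyr::bind_rows(d, tibble::tibble(age = 100, lambda_hat = 99))
  d2$quality <- c("ok", "ok", "ok", "nonpositive_slope")
  fit2 <- suppressMessages(estimate_decay_rate(d2))
  expect_identical(fit2$n, 3L)
  expect_equal(fit2$k, 1.66e-4, tolerance = 1e-12)

  expect_error(estimate_decay_rate(d[1:2, ]), "3 usable")
})

test_that("free-intercept mode recovers a nonzero intercept exactly", {
  # data generated with an intercept: through-origin is biased, the
  # free-intercept fit recovers both parameters
  d <- tibble::tibble(age = seq(20, 278, length.out = 12))
  d$lambda_hat <- 0.002 + 1.5e-4 * d$age
  fit <- estimate_decay_rate(d, mode = "free_intercept")
  expect_equal(fit$free_intercept$slope, 1.5e-4, tolerance = 1e-10)
  expect_equal(fit$free_intercept$intercept, 0.002, tolerance = 1e-10)
  expect_gt(fit$through_origin$slope, 1.5e-4)  # documented bias
})

test_that("cohort tables join without silent drops", {
  meta <- tibble::tibble(sample_id = sprintf("s%02d", 1:71),
                         collection_year = 1940 + (1:71),
                         age = 75 - (1:71))
  stats <- tibble::tibble(sample_id = meta$sample_id,
                          lambda_hat = 1e-4 * meta$age)
  stats$lambda_hat[5] <- NA  # missing lambda keeps its row
  tab <- cohort_table(stats, meta)
  expect_identical(nrow(tab), 71L)
  expect_true(is.na(tab$lambda_hat[5]))

  expect_error(cohort_table(
    tibble::tibble(sample_id = "zz", lambda_hat = 1), meta
  ), "unknown sample")
})

test_that("sequential ANOVA matches the projection oracle exactly", {
  # balanced small-integer table, 8 rows, 2 groups
  d <- tibble::tibble(
    x = c(1, 2, 3, 4, 1, 2, 3, 4),
    g = rep(c("a", "b"), each = 4),
    y = c(2, 3, 5, 6, 4, 6, 7, 10)
  )
  fit <- ancova(d, y, x, g)
  oracle <- seq_ss_oracle(d$y, d$x, d$g)
  expect_identical(fit$table$term[4], "Residuals")
  expect_equal(fit$table$sum_sq,
               unname(oracle[c("covariate", "factor", "interaction",
                               "residual")]),
               tolerance = 1e-10)
  # sequential SS (terms + residual) sum to total SS; dfs sum to n - 1
  expect_equal(sum(fit$table$sum_sq), sum((d$y - mean(d$y))^2),
               tolerance = 1e-10)
  expect_identical(as.integer(sum(fit$table$df)), nrow(d) - 1L)
})

test_that("ancova flags slope versus intercept differences correctly", {
  set.seed(7)
  x <- rep(seq(20, 278, length.out = 20), 2)
  g <- rep(c("nuclear", "organelle"), each = 20)

  # same slope, intercepts 5 residual SDs apart -> intercepts_differ
  y <- 1e-4 * x + ifelse(g == "organelle", -5, 0) + rnorm(40)
  fit <- ancova(tibble::tibble(x = x, g = g, y = y), y, x, g)
  expect_identical(fit$conclusion, "intercepts_differ")

  # clearly different slopes -> slopes_differ
  y2 <- ifelse(g == "organelle", 5e-2, 1e-2) * x + rnorm(40)
  fit2 <- ancova(tibble::tibble(x = x, g = g, y = y2), y, x, g)
  expect_identical(fit2$conclusion, "slopes_differ")

  expect_error(ancova(tibble::tibble(x = x, g = "one", y = y), y, x, g),
               "2 levels")
})

test_that("null interaction p-values are uniform (KS at 500 replicates)", {
  set.seed(101)
  x <- rep(seq(20, 278, length.out = 15), 2)
  g <- rep(c("a", "b"), each = 15)
  pvals <- replicate(500, {
    y <- 0.001 * x + rnorm(30)
    ancova(tibble::tibble(x = x, g = g, y = y), y, x, g)$interaction_p
  })
  expect_true(all(pvals >= 0 & pvals <= 1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})
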