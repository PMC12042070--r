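test_that("collinear data give exact major axis fits", {
  x <- 1:10
  fit <- fit_major_axis(x, x)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r, 1)
  expect_equal(fit$r2_identity, 1)
  expect_equal(fit$slope_ci, c(1, 1))
})

test_that("major axis slope matches the covariance eigenvector oracle", {
  withr::with_seed(21, {
    for (i in 1:10) {
      x <- rnorm(20)
      y <- 0.5 * x + rnorm(20, sd = 0.7)
      fit <- fit_major_axis(x, y)
      ev <- eigen(cov(cbind(x, y)))$vectors[, 1]
      expect_equal(fit$slope, ev[2] / ev[1], tolerance = 1e-10)
    }
  })
})

test_that("major axis regression is symmetric under axis exchange", {
  withr::with_seed(22, {
    x <- rnorm(50)
    y <- 1.3 * x + rnorm(50, sd = 0.5)
    expect_equal(fit_major_axis(y, x)$slope, 1 / fit_major_axis(x, y)$slope,
                 tolerance = 1e-12)
  })
})

test_that("RMA slope is the sign-corrected SD ratio", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(fit_rma(x, 2 * x + 1)$slope, 2)
  expect_equal(fit_rma(x, 2 * x + 1)$intercept, 1)
  withr::with_seed(23, {
    x <- rnorm(100); y <- -0.4 * x + rnorm(100, sd = 2)
    fit <- fit_rma(x, y)
    expect_equal(fit$slope^2, var(y) / var(x), tolerance = 1e-12)
    expect_equal(sign(fit$slope), sign(cor(x, y)))
  })
})

test_that("RMA is scale-equivariant; MA responds to uniform rescaling", {
  withr::with_seed(24, {
    x <- rnorm(40); y <- x + rnorm(40, sd = 0.5)
    k <- 7.3
    # RMA: rescaling one axis rescales the slope (true equivariance)
    expect_equal(fit_rma(x, k * y)$slope, k * fit_rma(x, y)$slope,
                 tolerance = 1e-12)
    expect_equal(fit_rma(x / k, y)$slope, k * fit_rma(x, y)$slope,
                 tolerance = 1e-12)
    # MA is equivariant only under rescaling both axes together; one-axis
    # rescaling changes the perpendicular metric and is not equivariant
    expect_equal(fit_major_axis(k * x, k * y)$slope,
                 fit_major_axis(x, y)$slope, tolerance = 1e-12)
  })
})

test_that("errors-in-both-variables simulation recovers slope 1 within the CI", {
  withr::with_seed(25, {
    truth <- rnorm(500, sd = 2)
    x <- truth + rnorm(500, sd = 0.5)
    y <- truth + rnorm(500, sd = 0.5)
    fit <- fit_rma(x, y)
    expect_gt(1, fit$slope_ci[1])
    expect_lt(1, fit$slope_ci[2])
    fit_ma <- fit_major_axis(x, y)
    expect_true(fit_ma$slope_ci[1] < 1 && 1 < fit_ma$slope_ci[2])
  })
})

test_that("confidence intervals contain their point estimates", {
  withr::with_seed(26, {
    for (i in 1:10) {
      x <- rnorm(15); y <- x + rnorm(15)
      for (fit in list(fit_major_axis(x, y), fit_rma(x, y))) {
        expect_true(fit$slope_ci[1] <= fit$slope,
                    info = paste(fit$method, "slope lo"))
        expect_true(fit$slope >= fit$slope_ci[1] && fit$slope <= fit$slope_ci[2])
        expect_true(fit$intercept >= fit$intercept_ci[1] &&
                      fit$intercept <= fit$intercept_ci[2])
      }
    }
  })
})

test_that("R^2 about the identity line follows its definition", {
  x <- c(1, 2, 3); y <- x
  expect_equal(r2_about_identity(x, y), 1)
  # constant offset: identity line can fit worse than the mean
  y2 <- c(5, 5.1, 4.9)
  expect_lt(r2_about_identity(c(1, 2, 3), y2), 0)
  withr::with_seed(27, {
    x <- rnorm(30); y <- x + rnorm(30, sd = 0.3)
    expect_equal(r2_about_identity(x, y),
                 1 - sum((y - x)^2) / sum((y - mean(y))^2))
  })
})

test_that("degenerate inputs raise explicit errors", {
  expect_error(fit_major_axis(1:2, 2:1), "at least 3")
  expect_error(fit_major_axis(c(1, 2, 3), c(2, 2, 2)), "covariance")
  expect_error(fit_rma(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(fit_rma(c(1, 2, 3), c(2, 2, 2)), "zero variance")
  expect_error(fit_rma(c(-1, 0, 1), c(2, 0, 2)), "orrelation")
  expect_error(r2_about_identity(c(1, 2), c(3, 3)), "variance")
})
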