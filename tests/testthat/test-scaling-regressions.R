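test_that("noiseless scaling data are recovered essentially exactly", {
  withr::with_seed(31, {
    x <- 10^runif(50, -3, 3)
  })
  y <- 10^(2 - 0.9 * log10(x))
  law <- fit_loglog(x, y, seed = 31L)
  expect_equal(law$intercept, 2, tolerance = 1e-2)
  expect_equal(law$slope, -0.9, tolerance = 1e-2)
  expect_lt(law$sigma, 0.01)
})

test_that("posterior medians recover known parameters within 3 posterior SDs", {
  withr::with_seed(32, {
    x <- 10^runif(500, -4, 4)
    y <- 10^(-0.5 - 0.94 * log10(x) + rnorm(500, 0, 1))
  })
  law <- fit_loglog(x, y, seed = 32L)
  expect_lt(abs(law$intercept - (-0.5)), 3 * sd(law$draws$intercept))
  expect_lt(abs(law$slope - (-0.94)), 3 * sd(law$draws$slope))
  expect_lt(abs(law$sigma - 1), 3 * sd(law$draws$sigma))
})

test_that("posterior predictive quantiles reduce and order correctly", {
  # single draw: exact lognormal quantiles
  law <- scaling_law(intercept = 2, slope = -0.9, sigma = 0.5)
  m <- c(0.01, 1, 100)
  expect_equal(posterior_predictive_quantile(law, m, 0.5),
               10^(2 - 0.9 * log10(m)))
  expect_equal(posterior_predictive_quantile(law, m, 0.9),
               10^(2 - 0.9 * log10(m) + 0.5 * qnorm(0.9)))
  # degenerate sigma: all quantiles collapse onto the line
  law0 <- scaling_law(2, -0.9, 0)
  expect_equal(posterior_predictive_quantile(law0, m, 0.123),
               10^(2 - 0.9 * log10(m)))
  # monotone in q, for a genuinely multi-draw law
  withr::with_seed(33, {
    x <- 10^runif(80, -2, 2); y <- 10^(1 - 0.7 * log10(x) + rnorm(80, 0, 0.6))
  })
  lawf <- fit_loglog(x, y, seed = 33L)
  qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  vals <- vapply(qs, function(q) posterior_predictive_quantile(lawf, 3.7, q),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
  # identical draws collapse to the single-normal quantile
  law_rep <- scaling_law(1.5, -0.8, 0.4)
  law_rep$draws <- law_rep$draws[rep(1, 50), ]
  expect_equal(posterior_predictive_quantile(law_rep, 2, 0.8),
               10^(1.5 - 0.8 * log10(2) + 0.4 * qnorm(0.8)), tolerance = 1e-7)
})

test_that("mixture quantile matches a large Monte Carlo predictive sample", {
  withr::with_seed(34, {
    x <- 10^runif(100, -2, 2)
    y <- 10^(0.5 - 0.6 * log10(x) + rnorm(100, 0, 0.8))
    law <- fit_loglog(x, y, seed = 34L)
    d <- law$draws[sample.int(nrow(law$draws), 4e5, replace = TRUE), ]
    sim <- d$intercept + d$slope * log10(5) + rnorm(4e5, 0, d$sigma)
    for (q in c(0.1, 0.5, 0.9)) {
      expect_lt(abs(log10(posterior_predictive_quantile(law, 5, q)) -
                      quantile(sim, q, names = FALSE)), 0.02)
    }
  })
})

test_that("median demand prediction follows the fitted line", {
  law <- scaling_law(-1, 0.87, 0)
  expect_equal(predict_median_demand(law, 100), 10^(-1 + 0.87 * 2))
  # simulated Kleiber-style law: median prediction within 5% of the curve
  withr::with_seed(35, {
    x <- 10^runif(400, -2, 6)
    y <- 10^(0.2 + 0.87 * log10(x) + rnorm(400, 0, 0.3))
  })
  fitted <- fit_loglog(x, y, seed = 35L)
  masses <- 10^c(0, 2, 4)
  expect_equal(predict_median_demand(fitted, masses),
               10^(0.2 + 0.87 * log10(masses)), tolerance = 0.05)
})

test_that("fit inputs are validated", {
  expect_error(fit_loglog(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_loglog(c(1, 2, -3), c(1, 2, 3)), "positive")
  expect_error(fit_loglog(c(1, 2, 3), c(1, 0, 3)), "positive")
  law <- scaling_law(1, 1, 0)
  expect_error(posterior_predictive_quantile(law, -1, 0.5), "mass")
  expect_error(posterior_predictive_quantile(law, 1, 1.5), "q must")
  law$draws <- law$draws[0, ]
  expect_error(posterior_predictive_quantile(law, 1, 0.5), "draws")
})

test_that("group routing rejects unknown taxa and reads schemas strictly", {
  tbl <- tibble::tibble(group = rep("fungus", 5), mass_g = 1:5,
                        response_value = 1:5,
                        response_type = "density_per_m2")
  expect_error(fit_scaling_laws(tbl, "density_per_m2"), "fungus")
  # prokaryotes have a density law but no metabolic law
  tbl2 <- tibble::tibble(group = "prokaryote", mass_g = c(1, 2, 3),
                         response_value = c(1, 2, 3),
                         response_type = "metabolic_kj_per_day")
  expect_error(fit_scaling_laws(tbl2, "metabolic_kj_per_day"), "prokaryote")

  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(group = "mammal", mass_g = 1), path,
                   row.names = FALSE)
  expect_error(read_scaling_table(path), "missing column")
})
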