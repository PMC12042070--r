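test_that("generation is deterministic under a seed and varies across seeds", {
  cfg <- generator_config(n_records = 50, n_scaling_obs_per_group = 20, seed = 9L)
  expect_identical(generate_scaling_table(cfg), generate_scaling_table(cfg))
  expect_identical(generate_forage_table(cfg), generate_forage_table(cfg))
  expect_identical(generate_field_records(cfg, 5), generate_field_records(cfg, 5))
  cfg2 <- generator_config(n_records = 50, n_scaling_obs_per_group = 20, seed = 10L)
  expect_false(identical(generate_forage_table(cfg)$records,
                         generate_forage_table(cfg2)$records))
})

test_that("noiseless scaling tables lie exactly on their generating lines", {
  laws <- list(mammal = c(intercept = -1, slope = -0.94, sigma = 0))
  dem <- list(mammal = c(intercept = 0.2, slope = 0.87, sigma = 0))
  cfg <- generator_config(n_records = 10, n_scaling_obs_per_group = 30,
                          groups = "mammal", density_laws = laws,
                          demand_laws = dem, seed = 12L)
  tbl <- generate_scaling_table(cfg)
  dens <- tbl[tbl$response_type == "density_per_m2", ]
  fit <- lm(log10(response_value) ~ log10(mass_g), data = dens)
  expect_equal(unname(coef(fit)), c(-1, -0.94), tolerance = 1e-10)
  expect_lt(sd(residuals(fit)), 1e-12)
})

test_that("generated scaling data recover their slopes within 3 SEs", {
  cfg <- generator_config(n_scaling_obs_per_group = 500, seed = 13L)
  tbl <- generate_scaling_table(cfg)
  inv <- tbl[tbl$group == "invertebrate" & tbl$response_type == "density_per_m2", ]
  fit <- summary(lm(log10(response_value) ~ log10(mass_g), data = inv))
  expect_lt(abs(fit$coefficients[2, 1] - (-0.94)), 3 * fit$coefficients[2, 2])
})

test_that("injected defect rows are produced in the exact configured counts", {
  cfg <- generator_config(n_records = 1000, frac_egg = 0.05,
                          frac_low_handling = 0.02, frac_missing_mass = 0.03,
                          seed = 14L)
  sim <- generate_forage_table(cfg)
  flt <- apply_exclusion_filters(sim$records)
  log <- flt$log
  expect_equal(log$n_excluded[log$rule == "egg_or_nonliving_prey"], 50L)
  # at least the injected counts; observed handling times can fall below the
  # floor naturally too (which is the reason the filter exists)
  expect_gte(log$n_failing[log$rule == "handling_time_floor"], 20L)
  expect_lte(log$n_excluded[log$rule == "missing_mass"], 30L)
  expect_equal(log$n_failing[log$rule == "missing_mass"], 30L)
  expect_equal(flt$n_retained, 1000L - sum(log$n_excluded))
})

test_that("true low/high densities are the stated quantiles of density draws", {
  cfg <- generator_config(n_records = 5, groups = "invertebrate",
                          density_laws = list(invertebrate = c(2, -0.94, 1)),
                          demand_laws = list(invertebrate = c(-1.2, 0.87, 0.3)),
                          seed = 15L)
  sim <- generate_forage_table(cfg)
  mn <- sim$records$prey_mass_g[1]
  withr::with_seed(16, {
    draws <- 10^(2 - 0.94 * log10(mn) + rnorm(1e5, 0, 1))
  })
  expect_lt(abs(log10(quantile(draws, 0.1, names = FALSE)) -
                  log10(sim$truth$Nlow[1])), 0.02)
  expect_lt(abs(log10(quantile(draws, 0.9, names = FALSE)) -
                  log10(sim$truth$Nhigh[1])), 0.02)
})

test_that("noiseless field records are reproduced exactly by direct prediction", {
  cfg <- noiseless_config(10, seed = 17L)
  rec <- generate_field_records(cfg, 6)
  out <- predict_field_study(rec, IS = cfg$IS_true)
  expect_equal(out$a_pred, rec$observed_a, tolerance = 1e-12)
  expect_equal(out$h_pred, rec$observed_h, tolerance = 1e-12)
  # stated energy density agrees with the composition conversion path
  expect_equal(rec$energy_density_kj_g,
               energy_density_from_composition(rec$pct_protein, rec$pct_fat))
})

test_that("generator configuration is validated", {
  expect_error(generator_config(groups = character(0)), "at least one")
  expect_error(generator_config(groups = "prokaryote"), "prokaryote")
  expect_error(generator_config(IS_true = 1), "IS_true")
  expect_error(generator_config(q_low = 0.9, q_high = 0.1))
  expect_error(generator_config(frac_egg = 0.7, frac_low_handling = 0.5))
})
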