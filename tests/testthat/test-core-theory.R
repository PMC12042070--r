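test_that("feeding rates match the linear and Holling type II forms", {
  expect_equal(feeding_rate_linear(1, 0), 0)
  expect_equal(feeding_rate_linear(2, 3), 6)
  expect_equal(feeding_rate_linear(0.5, 10), 5)

  fr <- functional_response(1, 1)
  expect_equal(feeding_rate_holling2(fr, 1), 0.5)       # N = 1/(ah)
  expect_lt(abs(feeding_rate_holling2(fr, 1e9) - 1), 1e-8)  # asymptote 1/h
  fr2 <- functional_response(1, 1 / 9)
  # N = 9 is the half-saturation density 1/(ah); f = f_max/2 = 4.5
  expect_equal(feeding_rate_holling2(fr2, 9), 4.5)

  expect_error(feeding_rate_linear(0, 1), "space clearance")
  expect_error(feeding_rate_holling2(fr, -1), "density")
})

test_that("Holling type II reduces to the linear form as handling vanishes", {
  a <- 0.37
  N <- 10^seq(-4, 2, length.out = 20)
  h <- 1e-10 / (a * N)  # keeps a*h*N = 1e-10 < 1e-8 across the grid
  f2 <- feeding_rate_holling2(functional_response(a, h), N)
  expect_lt(max(abs(f2 / feeding_rate_linear(a, N) - 1)), 1e-6)
})

test_that("Holling type II output is bounded by the maximum feeding rate", {
  withr::with_seed(11, {
    for (i in 1:50) {
      fr <- functional_response(10^runif(1, -6, 6), 10^runif(1, -6, 6))
      N <- 10^runif(20, -8, 8)
      f <- feeding_rate_holling2(fr, N)
      expect_true(all(f <= fr$f_max))  # strict in exact arithmetic
      expect_true(all(diff(feeding_rate_holling2(fr, sort(N))) >= 0))
    }
  })
})

test_that("space clearance rate solves the low-density demand balance", {
  ctx <- energetic_context(5.6, 5.6, 1, 1, 9)
  expect_equal(predict_space_clearance(ctx), 1)

  ctx2 <- energetic_context(2 * 5.6, 5.6, 1, 1, 9)
  expect_equal(predict_space_clearance(ctx2), 2)  # proportional in D

  # root-finder oracle: a solves D = a * Nlow * E * MN
  ctx3 <- energetic_context(10, 5.6, 0.5, 100, 100)
  a_oracle <- uniroot(function(a) a * 100 * 5.6 * 0.5 - 10,
                      c(1e-12, 1e6), tol = 1e-14)$root
  expect_equal(predict_space_clearance(ctx3), a_oracle, tolerance = 1e-8)
  expect_equal(predict_space_clearance(ctx3), 10 / (100 * 5.6 * 0.5))
})

test_that("handling time solves the saturation condition at high density", {
  ctx <- energetic_context(5.6, 5.6, 1, 1, 9, saturation = 0.9)
  expect_equal(predict_handling_time(ctx), 0.9 / (9 * 0.1))  # = 1

  # IS -> 0 implies h -> 0 (no saturation needs no handling limit)
  ctx_small <- energetic_context(5.6, 5.6, 1, 1, 9, saturation = 1e-8)
  expect_lt(predict_handling_time(ctx_small), 1e-8)

  # bisection oracle: h solves IS = f(Nhigh; a, h) * h with rule-1 a
  ctx4 <- energetic_context(2, 5.6, 0.1, 50, 500, saturation = 0.9)
  a <- predict_space_clearance(ctx4)
  g <- function(h) a * 500 / (1 + a * h * 500) * h - 0.9
  lo <- 1e-12; hi <- 1e8
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  expect_equal(predict_handling_time(ctx4), lo, tolerance = 1e-6)
})

test_that("saturation at density behaves as a Michaelis-Menten fraction", {
  fr <- functional_response(2, 0.25)
  expect_equal(saturation_at_density(fr, 0), 0)
  expect_equal(saturation_at_density(fr, 1 / (2 * 0.25)), 0.5)
  ctx <- random_contexts(50, seed = 3)
  fr2 <- predict_functional_response(ctx)
  expect_equal(saturation_at_density(fr2, ctx$Nhigh), ctx$IS, tolerance = 1e-12)
})

test_that("the two rules and their corollaries hold as identities", {
  ctx <- random_contexts(500, seed = 5)
  fr <- predict_functional_response(ctx)
  # rule 1: energy intake at low density equals demand
  expect_equal(demand_check(fr, ctx), ctx$D, tolerance = 1e-12)
  # rule 2: saturation at high density equals I_S
  expect_equal(saturation_at_density(fr, ctx$Nhigh), ctx$IS, tolerance = 1e-12)
  # half-saturation corollary
  expect_equal(1 / (fr$a * fr$h),
               half_saturation_predicted(ctx$Nhigh, ctx$IS), tolerance = 1e-12)
  # a-from-h consistency
  expect_equal(predicted_a_from_h(fr$h, ctx$Nhigh, ctx$IS), fr$a,
               tolerance = 1e-12)
})

test_that("half-saturation and a-from-h closed forms match stated values", {
  expect_equal(half_saturation_predicted(7, 0.5), 7)
  expect_equal(half_saturation_predicted(9, 0.9), 1)
  expect_equal(predicted_a_from_h(1, 1, 0.5), 1)
  expect_equal(predicted_a_from_h(2, 1, 0.5), 0.5)  # h doubled -> a halved
  expect_error(half_saturation_predicted(9, 1), "I_S")
  expect_error(predicted_a_from_h(0, 1, 0.5), "handling")
})

test_that("demand check returns energy intake at low density", {
  fr <- functional_response(1, 0.01)
  ctx <- energetic_context(5.6, 5.6, 1, 1, 9)
  expect_equal(demand_check(fr, ctx), 5.6)  # a=1, Nlow=1, E=5.6, MN=1
})

test_that("predictions are monotone in the context quantities", {
  base <- list(D = 3, E = 5.6, MN = 0.2, Nlow = 10, Nhigh = 200, IS = 0.9)
  mk <- function(p) energetic_context(p$D, p$E, p$MN, p$Nlow, p$Nhigh, p$IS)
  bump <- function(field, factor) {
    p <- base; p[[field]] <- p[[field]] * factor; mk(p)
  }
  a0 <- predict_space_clearance(mk(base))
  h0 <- predict_handling_time(mk(base))
  expect_gt(predict_space_clearance(bump("D", 2)), a0)
  expect_lt(predict_space_clearance(bump("Nlow", 2)), a0)
  expect_lt(predict_space_clearance(bump("E", 2)), a0)
  expect_lt(predict_space_clearance(bump("MN", 2)), a0)
  expect_lt(predict_handling_time(bump("D", 2)), h0)
  expect_lt(predict_handling_time(bump("Nhigh", 2)), h0)
  p <- base; p$IS <- 0.95
  expect_gt(predict_handling_time(mk(p)), h0)
})

test_that("context validation enforces the domain invariants", {
  expect_error(energetic_context(-1, 5.6, 1, 1, 9), "demand")
  expect_error(energetic_context(1, 5.6, 1, 9, 1), "density_low")
  expect_error(energetic_context(1, 5.6, 1, 1, 9, saturation = 1), "I_S")
  expect_error(energetic_context(1, 5.6, 1, 1, 9, saturation = 0), "I_S")
  expect_error(energetic_context(1, 5.6, 0, 1, 9), "prey mass")
  # degenerate Nlow = Nhigh is allowed and keeps h finite
  ctx <- energetic_context(1, 5.6, 1, 5, 5)
  expect_true(is.finite(predict_handling_time(ctx)))
})

test_that("assimilation efficiency rescales the effective energy density", {
  full <- energetic_context(5.6, 5.6, 1, 1, 9)
  half <- energetic_context(5.6, 5.6, 1, 1, 9, assimilation = 0.5)
  expect_equal(predict_space_clearance(half), 2 * predict_space_clearance(full))
  fr <- predict_functional_response(half)
  expect_equal(demand_check(fr, half), half$D, tolerance = 1e-12)
})

test_that("unit helpers convert composition and volumetric rates", {
  expect_equal(energy_density_from_composition(20, 5),
               0.01 * (20 * 16.74 + 5 * 33.47))
  expect_equal(energy_density_from_composition(0, 0), 0)
  expect_error(energy_density_from_composition(80, 30), "composition")
  expect_equal(clearance_volume_to_area(3, 2), 1.5)
  expect_error(clearance_volume_to_area(1, 0), "depth")
})
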