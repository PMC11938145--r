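test_that("full irrigation quota follows the refill rule", {
  s <- soil_params(theta_fc = 0.30, theta_v = 0.15, z_r = 40)
  expect_equal(full_irrigation_quota(s), 28.8)
  s2 <- soil_params(theta_fc = 0.3054, theta_v = 0.20, z_r = 40)
  expect_equal(full_irrigation_quota(s2), 17.9664, tolerance = 1e-4)
  s3 <- soil_params(theta_fc = 0.30, theta_v = 0.9 * 0.30)
  expect_warning(q <- full_irrigation_quota(s3), "zero quota")
  expect_equal(q, 0)
  expect_error(soil_params(theta_fc = 0.2, theta_rwp = 0.3), "theta_rwp")
})

test_that("water balance rearranges to actual ET and rejects negatives", {
  expect_equal(actual_et_from_balance(P = 50, I = 30, G = 5, D = 10, R = 5,
                                      dW = 10), 60)
  expect_equal(actual_et_from_balance(0, 0), 0)
  expect_error(actual_et_from_balance(P = 10, I = 0, D = 20), "negative ET_a")
  # closure: the balance identity inverts for random stage records
  set.seed(1)
  for (i in 1:20) {
    P <- runif(1, 0, 100); I <- runif(1, 0, 100); G <- runif(1, 0, 10)
    et <- runif(1, 0, P + I + G)
    dW <- P + I + G - et
    expect_equal(actual_et_from_balance(P, I, G, dW = dW), et)
  }
})

test_that("nitrogen response is the floored quadratic", {
  p <- list(a = -0.1, b = 48, c = 2000)
  expect_equal(nitrogen_potential_yield(p, 240), 7760)
  expect_equal(nitrogen_potential_yield(p, 0), 2000)
  # calculus: vertex maximizes
  grid <- seq(0, 480, by = 1)
  expect_equal(grid[which.max(nitrogen_potential_yield(p, grid))], 240)
  expect_warning(y <- nitrogen_potential_yield(list(a = -1, b = 0, c = -5), 1),
                 "floored")
  expect_equal(y, 0)
})

test_that("Jensen yield multiplies capped sensitivity-weighted ratios", {
  expect_equal(jensen_yield(1000, 100, 100, 0.5), 1000) # all ratios 1
  expect_equal(jensen_yield(1000, 50, 100, 0.532), 1000 * 0.5^0.532,
               tolerance = 1e-10)
  expect_equal(1000 * 0.5^0.532, 691.58, tolerance = 0.01)
  expect_equal(jensen_yield(1000, c(0, 80), c(60, 80), c(0.4, 0.3)), 0)
  # over-supply is capped at the potential, never rewarded
  expect_equal(jensen_yield(1000, 150, 100, 0.5), 1000)
  expect_error(jensen_yield(1000, 50, c(100, 90), 0.5), "equal length")
})

test_that("Jensen yield is monotone in stage water up to the potential", {
  lam <- c(0.086, 0.314, 0.532, 0.208, 0.163)
  et_m <- rep(100, 5)
  y_prev <- -1
  for (f in seq(0.1, 1, by = 0.1)) {
    y <- jensen_yield(5000, rep(100 * f, 5), et_m, lam)
    expect_gt(y, y_prev)
    y_prev <- y
  }
  expect_equal(jensen_yield(5000, et_m, et_m, lam), 5000)
})

test_that("equivalent yield rescales by relative price", {
  expect_equal(equivalent_yield(8000, 4, 4), 8000)  # reference crop
  expect_equal(equivalent_yield(6000, 2, 4), 3000)
  expect_equal(equivalent_yield(0, 2, 4), 0)
  expect_error(equivalent_yield(1, 1, 0), "positive")
})

test_that("amendment quadratic and recycling update behave", {
  z <- list(a = 0, b = 0, c = 0, d = 0, e = 0, f = 0)
  expect_equal(amendment_factor(z, 10, 10), 0)
  z$f <- 0.12
  expect_equal(amendment_factor(z, 0, 0), 0.12)
  expect_equal(amendment_factor(list(a = 1, b = 1, c = 1, d = 0, e = 0, f = 0),
                                2, 3), 19)
  expect_equal(recycled_stage_value(1000, 0.05), 1050)
  expect_equal(recycled_stage_value(7, 0), 7)
  expect_error(recycled_stage_value(1000, -1.2), "nonphysical")
})

test_that("biomass production is the linear chain of factors", {
  expect_equal(biomass_production(1, 8000, 1.2, 0.9, 1), 8640)
  expect_equal(biomass_production(1, 8000, 1.2, 0, 1), 0)
  expect_equal(biomass_production(2, 8000, 1.2, 0.9, 1),
               2 * biomass_production(1, 8000, 1.2, 0.9, 1))
  # degree-1 homogeneity in each linear factor
  expect_equal(biomass_production(1, 8000, 2 * 1.2, 0.9, 1),
               2 * 8640)
})
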