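test_that("soil water bounds follow the storage formula", {
  s <- soil_params(theta_fc = 0.3054, theta_rwp = 0.1272,
                   bulk_density = 1.2, z_r = 40)
  w <- soil_water_bounds(s)
  expect_equal(unname(w["W_min"]), 61.056)
  expect_equal(unname(w["W_max"]), 146.592)
  expect_lt(w["W_min"], w["W_max"])
})

test_that("membership is the anchored linear ramp", {
  sp <- list(sense = "max", best = 10, worst = 2)
  expect_equal(membership(10, sp), 1)
  expect_equal(membership(2, sp), 0)
  expect_equal(membership(6, sp), 0.5)
  expect_equal(membership(100, sp), 1) # clipped
  spm <- list(sense = "min", best = 2, worst = 10)
  expect_equal(membership(2, spm), 1)
  expect_equal(membership(10, spm), 0)
  expect_equal(membership(6, spm), 0.5)
  expect_error(membership(1, list(sense = "max", best = 3, worst = 3)),
               "differ")
})

test_that("max-min scalarization picks the weakest objective", {
  expect_equal(scalarize_maxmin(c(0.7, 0.4, 0.9, 0.6)), 0.4)
  expect_equal(scalarize_maxmin(rep(1, 4)), 1)
  expect_equal(scalarize_maxmin(c(0.7, 0.4, 0.9, 0.6)),
               scalarize_maxmin(c(0.4, 0.9, 0.6, 0.7)))
  expect_error(scalarize_maxmin(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("evaluate_objectives matches the hand-composed module chain", {
  # dual route: the vectorized core vs step-by-step exported primitives
  for (seed in c(2, 5)) {
    b <- default_bundle(seed)
    h <- hydro_scenario(b, "normal")
    set.seed(seed)
    w <- soil_water_bounds(b$soil)
    I1 <- matrix(runif(b$n_crops * b$n_stages, w["W_min"], w["W_max"]),
                 b$n_crops)
    I2 <- matrix(runif(b$n_crops * b$n_stages, w["W_min"], w["W_max"]),
                 b$n_crops)
    N1 <- runif(b$n_crops, b$bounds$N_min, b$bounds$N_max)
    N2 <- runif(b$n_crops, b$bounds$N_min, b$bounds$N_max)
    dec <- decision_vector(I1, I2, N1, N2, equal_alloc())
    fast <- evaluate_objectives(dec, b, h)
    slow <- eval_by_hand(dec, b, h)
    expect_equal(fast$NEB, slow$NEB, tolerance = 1e-10)
    expect_equal(fast$TCQ, slow$TCQ, tolerance = 1e-10)
    expect_equal(fast$WF, slow$WF, tolerance = 1e-10)
    expect_equal(fast$CF, slow$CF, tolerance = 1e-10)
  }
})

test_that("constraint residuals report slack and violations", {
  b <- default_bundle()
  h <- hydro_scenario(b, "normal")
  w <- soil_water_bounds(b$soil)
  eval_con <- build_constraints(b, equal_alloc())
  # boundary-feasible decision: irrigation pinned at the upper bound
  I <- matrix(w[["W_max"]], b$n_crops, b$n_stages)
  dec <- decision_vector(I, I, b$recommended_N, b$recommended_N, equal_alloc())
  res <- eval_con(dec, h)
  expect_equal(unname(res$slack["irr_upper"]), 0)
  expect_true(res$slack["irr_lower"] > 0)
  expect_true(res$feasible)
  # a violated allocation-sum constraint is reported with its magnitude
  bad <- dec
  bad$alloc <- structure(c(pr_straw = 0.3, pr_biochar = 0.3, pr_ele = 0.3,
                           pr_sell = 0.3),
                         class = c("straw_allocation", "numeric"))
  res_bad <- eval_con(bad, h)
  expect_equal(unname(res_bad$slack["alloc_sum"]), 1e-9 - 0.2)
  expect_false(res_bad$feasible)
})

test_that("single-objective solves beat random feasible decisions", {
  toy <- toy_instance(3)
  b <- toy$bundle; h <- toy$hydro
  for (objective in c("NEB", "WF")) {
    sol <- solve_single_objective(b, h, equal_alloc(), objective,
                                  seed = 1, n_starts = 2, maxit = 40)
    sense <- if (objective == "NEB") 1 else -1
    set.seed(42)
    w <- soil_water_bounds(b$soil)
    for (i in 1:25) {
      I1 <- matrix(runif(b$n_stages, w["W_min"], w["W_max"]), 1)
      I2 <- matrix(runif(b$n_stages, w["W_min"], w["W_max"]), 1)
      N <- runif(2, b$bounds$N_min, b$bounds$N_max)
      v <- evaluate_objectives(decision_vector(I1, I2, N[1], N[2],
                                               equal_alloc()), b, h)[[objective]]
      expect_gte(sense * sol$value - sense * v, -1e-3 * abs(sol$value))
    }
  }
})

test_that("the compromise solve is reproducible and within bounds", {
  toy <- toy_instance(8)
  s1 <- solve_allocation(toy$bundle, toy$hydro, equal_alloc(), seed = 5,
                         n_starts = 2, maxit = 40)
  s2 <- solve_allocation(toy$bundle, toy$hydro, equal_alloc(), seed = 5,
                         n_starts = 2, maxit = 40)
  expect_identical(s1$decision, s2$decision)
  expect_identical(s1$lambda, s2$lambda)
  expect_true(all(s1$memberships >= 0 & s1$memberships <= 1))
  expect_equal(s1$lambda, min(s1$memberships))
  w <- soil_water_bounds(toy$bundle$soil)
  expect_true(all(s1$decision$I_st >= w["W_min"] - 1e-9 &
                    s1$decision$I_st <= w["W_max"] + 1e-9))
  expect_true(all(s1$decision$N_st >= toy$bundle$bounds$N_min - 1e-9 &
                    s1$decision$N_st <= toy$bundle$bounds$N_max + 1e-9))
  expect_true(s1$residuals$feasible)
})

test_that("relaxing the nitrogen bound cannot reduce attainment", {
  toy <- toy_instance(4)
  sol <- solve_allocation(toy$bundle, toy$hydro, equal_alloc(), seed = 2,
                          n_starts = 2, maxit = 40)
  relaxed <- toy$bundle
  relaxed$bounds$N_max <- 1.5 * relaxed$bounds$N_max
  sol_r <- solve_allocation(relaxed, toy$hydro, equal_alloc(), seed = 2,
                            n_starts = 2, maxit = 40, specs = sol$specs)
  expect_gte(sol_r$lambda, sol$lambda - 0.02)
})

test_that("the grid oracle refuses oversized grids and refines monotonely", {
  b <- default_bundle()
  h <- hydro_scenario(b, "normal")
  specs <- list(NEB = list(sense = "max", best = 1, worst = 0),
                TCQ = list(sense = "max", best = 1, worst = 0),
                WF = list(sense = "min", best = 0, worst = 1),
                CF = list(sense = "min", best = 0, worst = 1))
  expect_error(brute_force_oracle(b, h, equal_alloc(), 5, specs),
               "grid too large")
  toy <- toy_instance(2)
  specs <- payoff_table(toy$bundle, toy$hydro, equal_alloc(), seed = 1,
                        n_starts = 2, maxit = 30)
  o2 <- brute_force_oracle(toy$bundle, toy$hydro, equal_alloc(), 2, specs)
  o3 <- brute_force_oracle(toy$bundle, toy$hydro, equal_alloc(), 3, specs)
  # the 3-point grid contains the 2-point grid
  expect_gte(o3$lambda, o2$lambda)
  expect_identical(o3$n_evaluated, 729L)
})
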