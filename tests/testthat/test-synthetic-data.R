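test_that("the treatment design is the published nine-row Latin square", {
  cfg <- study_config(seed = 1)
  d <- generate_design(cfg)
  expect_identical(length(unique(d$treatment)), 9L)
  expect_identical(nrow(d), 9L * cfg$n_crops)
  one <- d[!duplicated(d$treatment), ]
  # bijection between the nine (I, N) combinations and treatments
  expect_identical(anyDuplicated(paste(one$irrigation_level,
                                       one$nitrogen_level)), 0L)
  t5 <- one[one$treatment == "T5", ]
  expect_identical(t5$irrigation_level, "I2")
  expect_identical(t5$nitrogen_level, "N2")
  expect_identical(t5$additive_level, "B3S3")
  t1 <- one[one$treatment == "T1", ]
  expect_identical(paste(t1$irrigation_level, t1$nitrogen_level,
                         t1$additive_level), "I1 N1 B3S3")
  # half-and-half additive level carries 15-30-20 t/ha of each amendment
  b2 <- d[d$treatment == "T3", ] # T3 is B2+S2
  expect_equal(b2$biochar_t_ha, c(15, 30, 20))
  expect_equal(b2$straw_t_ha, c(15, 30, 20))
  # absolute rates follow the level multipliers
  expect_equal(d$irrigation_mm, d$irrigation_frac *
                 rep(cfg$full_irrigation, 9))
  expect_equal(d$nitrogen_kg_ha, d$nitrogen_frac *
                 rep(cfg$recommended_N, 9))
})

test_that("parameter generation is deterministic and well-signed", {
  b1 <- generate_parameters(study_config(seed = 99))
  b2 <- generate_parameters(study_config(seed = 99))
  expect_identical(b1, b2)
  b3 <- generate_parameters(study_config(seed = 100))
  expect_false(identical(b1, b3))

  expect_equal(b1$jensen[[1]]$lambda, c(0.086, 0.314, 0.532, 0.208, 0.163))
  for (ci in 1:3) {
    jp <- b1$jensen[[ci]]
    expect_lt(jp$a, 0) # concave nitrogen response
    vertex <- -jp$b / (2 * jp$a)
    expect_gt(vertex, 0)
    expect_lte(vertex, 2 * b1$recommended_N[ci])
    expect_true(all(jp$lambda > 0))
    # interior-stage maximum of the sensitivity exponents
    expect_true(which.max(jp$lambda) %in% 2:4)
  }
  expect_true(all(unlist(b1$prices) > 0))
  expect_true(all(vapply(b1$amendment, function(a) a$yield$a < 0, NA)))
})

test_that("nitrogen vertex follows -b/(2a)", {
  expect_equal(-48 / (2 * -0.1), 240) # hand-derived reference
  b <- default_bundle()
  jp <- b$jensen[[2]]
  expect_equal(-jp$b / (2 * jp$a), b$recommended_N[2], tolerance = 1e-10)
})

test_that("observations at zero noise reproduce the forward model exactly", {
  b <- default_bundle()
  d <- generate_design(study_config(seed = 42))
  o1 <- generate_observations(b, d, 0, seed = 1, n_replicates = 2)
  o2 <- generate_observations(b, d, 0, seed = 77, n_replicates = 2)
  expect_equal(o1$yield, o2$yield) # no noise: seed is irrelevant
  # replicates share the treatment-level truth
  expect_equal(o1$yield[o1$replicate == 1], o1$yield[o1$replicate == 2])
  expect_true(all(o1$yield >= 0) && all(o1$biomass >= 0))
  expect_true(all(o1$quality >= 0 & o1$quality <= 1))
})

test_that("observation noise is seeded, multiplicative and truncated", {
  b <- default_bundle()
  d <- generate_design(study_config(seed = 42))
  o1 <- generate_observations(b, d, 0.05, seed = 5)
  o2 <- generate_observations(b, d, 0.05, seed = 5)
  expect_identical(o1, o2)
  o3 <- generate_observations(b, d, 0.05, seed = 6)
  expect_false(identical(o1$yield, o3$yield))
  expect_true(all(o1$yield >= 0))
  expect_error(generate_observations(b, d, -0.1), "non-negative")
  truth <- generate_observations(b, d, 0, n_replicates = 1)
  # relative deviations scale like the cv
  rel <- abs(o1$yield / rep(truth$yield, 3) - 1)
  expect_lt(median(rel), 3 * 0.05)
})

test_that("quadratic responses are recovered from observations", {
  cfg <- study_config(seed = 42)
  b <- default_bundle()
  d <- generate_design(cfg)
  obs0 <- generate_observations(b, d, 0, seed = 1)
  for (crop in b$crops) {
    fit <- fit_n_response(obs0, b, d, crop)
    jp <- b$jensen[[match(crop, b$crops)]]
    expect_equal(fit$a, jp$a, tolerance = 1e-6)
    expect_equal(fit$b, jp$b, tolerance = 1e-6)
    expect_equal(fit$c, jp$c, tolerance = 1e-6)
  }
  qfit <- fit_quality_surface(obs0, b, d, "corn")
  qp <- b$quality[[2]]
  expect_equal(qfit$ac, qp$ac, tolerance = 1e-6)
  expect_equal(qfit$fc, qp$fc, tolerance = 1e-6)

  ad <- generate_amendment_design(cfg)
  aobs0 <- generate_observations(b, ad, 0, seed = 1)
  afit <- fit_amendment(aobs0, b, ad, "corn", "yield")
  gen <- b$amendment[[2]]$yield
  for (k in c("a", "b", "d", "e")) {
    expect_equal(afit[[k]], gen[[k]], tolerance = 1e-6)
  }
})

test_that("recovery error shrinks as observation noise shrinks", {
  cfg <- study_config(seed = 42)
  b <- default_bundle()
  d <- generate_design(cfg)
  err_at <- function(cv) {
    e <- vapply(1:3, function(s) {
      obs <- generate_observations(b, d, cv, seed = s)
      fit <- fit_n_response(obs, b, d, "corn")
      abs(fit$a / b$jensen[[2]]$a - 1)
    }, 0)
    mean(e)
  }
  e0 <- err_at(0); e1 <- err_at(0.01); e5 <- err_at(0.05)
  expect_lt(e0, 1e-8)
  expect_lt(e1, e5)
})
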