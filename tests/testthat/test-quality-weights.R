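test_that("crop quality is the bivariate quadratic, clipped to [0,1]", {
  z <- list(ac = 0, bc = 0, cc = 0, dc = 0, ec = 0, fc = 0.5)
  expect_equal(crop_quality(z, 100, 300), 0.5)
  q <- list(ac = -1e-6, bc = 0, cc = 4e-4, dc = 0, ec = 0, fc = 0)
  expect_equal(crop_quality(q, 200, 0), 0.04)
  big <- list(ac = 0, bc = 0, cc = 1, dc = 0, ec = 0, fc = 0)
  expect_warning(v <- crop_quality(big, 10, 0), "clipped")
  expect_equal(v, 1)
  # structural symmetry: swapping (N, irrigation) with their coefficients
  a <- list(ac = -2e-6, bc = -3e-6, cc = 1e-3, dc = 2e-3, ec = 1e-6, fc = 0.1)
  swapped <- list(ac = a$bc, bc = a$ac, cc = a$dc, dc = a$cc, ec = a$ec,
                  fc = a$fc)
  expect_equal(crop_quality(a, 120, 250, clip = FALSE),
               crop_quality(swapped, 250, 120, clip = FALSE))
})

test_that("recycled quality applies the amendment and stays in [0,1]", {
  z <- list(a = 0, b = 0, c = 0, d = 0, e = 0, f = 0)
  expect_equal(recycled_quality(0.6, z, 10, 10), 0.6)
  z$f <- 0.1
  expect_equal(recycled_quality(0.6, z, 0, 0), 0.66)
  z$f <- 0.9
  expect_equal(recycled_quality(0.9, z, 0, 0), 1) # clipped at 1
  z$f <- -1.5
  expect_error(recycled_quality(0.5, z, 0, 0), "nonphysical")
})

test_that("total comprehensive quality averages the two stages", {
  expect_equal(total_comprehensive_quality(1, 0.6, 0.6), 0.6)
  w <- rep(1 / 3, 3)
  expect_equal(total_comprehensive_quality(w, c(0.3, 0.6, 0.9),
                                           c(0.3, 0.6, 0.9)), 0.6)
  expect_equal(total_comprehensive_quality(w, rep(1, 3), rep(1, 3)), 1)
  expect_error(total_comprehensive_quality(w, c(0.5, 0.5), c(0.5, 0.5)),
               "mismatch")
  # permutation invariance under a consistent crop reordering
  w2 <- c(0.5, 0.3, 0.2); q1 <- c(0.2, 0.5, 0.8); q2 <- c(0.4, 0.6, 0.7)
  p <- c(3, 1, 2)
  expect_equal(total_comprehensive_quality(w2, q1, q2),
               total_comprehensive_quality(w2[p], q1[p], q2[p]))
})

test_that("AHP weights come from the principal eigenvector", {
  r <- ahp_weights(matrix(c(1, 1/3, 3, 1), 2, 2))
  expect_equal(r$weights, c(0.75, 0.25))
  expect_equal(r$cr, 0)
  r4 <- ahp_weights(matrix(1, 4, 4))
  expect_equal(r4$weights, rep(0.25, 4))
  expect_true(r4$consistent)
  expect_error(ahp_weights(matrix(c(1, 2, 3, 1), 2, 2)), "reciprocal")
  # a perfectly consistent matrix reproduces its generating ratios
  w <- c(0.4, 0.3, 0.2, 0.1)
  r <- ahp_weights(ahp_matrix_from_weights(w))
  expect_equal(r$weights, w, tolerance = 1e-10)
  expect_lt(r$cr, 1e-10)
})

test_that("entropy weighting matches an independent implementation", {
  X <- matrix(c(0, 0.1, 1,
                0, 0.5, 1), ncol = 2)
  # brute-force oracle, written out longhand
  oracle <- function(X) {
    m <- nrow(X)
    Z <- apply(X, 2, function(x) (x - min(x)) / (max(x) - min(x)))
    e <- apply(Z, 2, function(z) {
      p <- z / sum(z); p <- p[p > 0]; -sum(p * log(p)) / log(m)
    })
    (1 - e) / sum(1 - e)
  }
  expect_equal(entropy_weights(X), oracle(X), tolerance = 1e-12)
  # duplicated indicators share the weight equally
  Y <- matrix(c(1, 5, 9, 1, 5, 9), ncol = 2)
  expect_equal(entropy_weights(Y), c(0.5, 0.5))
  expect_equal(sum(entropy_weights(X)), 1)
  expect_error(entropy_weights(matrix(3, 4, 2)), "constant")
  # cost-type orientation reverses the column
  Xc <- matrix(c(0, 0.1, 1, 1, 0.9, 0), ncol = 2)
  w <- entropy_weights(Xc, benefit = c(TRUE, FALSE))
  expect_equal(w, c(0.5, 0.5))
})

test_that("game-theoretic combination solves the Nash least-squares system", {
  w1 <- c(0.6, 0.4)
  same <- game_combination(list(w1, w1))
  expect_equal(same$weights, w1)
  orth <- game_combination(list(c(1, 0), c(0, 1)))
  expect_equal(orth$weights, c(0.5, 0.5))
  expect_equal(sum(orth$alpha), 1)
  three <- game_combination(list(c(0.5, 0.3, 0.2), c(0.4, 0.4, 0.2),
                                 c(0.2, 0.3, 0.5)))
  expect_equal(sum(three$weights), 1)
  expect_true(all(three$weights >= 0))
  expect_error(game_combination(list(c(0.5, 0.5), c(0.2, 0.3, 0.5))),
               "equal length")
})
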