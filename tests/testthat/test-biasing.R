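test_that("softmin is a tight smooth lower bound on the minimum", {
  expect_equal(softmin(2, 2, 40), 2 - log(2) / 40, tolerance = 1e-15)
  ## far-apart branches: deviation below 1e-12 (the e^-120 tail)
  expect_equal(softmin(2, 5, 40), 2, tolerance = 1e-12)
  set.seed(3L)
  d1 <- runif(200L, 0, 6)
  d2 <- runif(200L, 0, 6)
  sm <- softmin(d1, d2, 40)
  expect_true(all(sm <= pmin(d1, d2)))
  expect_true(all(sm >= pmin(d1, d2) - log(2) / 40))
  ## monotone in each argument
  expect_true(all(diff(softmin(seq(0, 3, 0.01), 1.5, 40)) >= 0))
  ## no overflow for extreme arguments
  expect_equal(softmin(1e6, 1e-6, 40), 1e-6, tolerance = 1e-12)
  expect_error(softmin(1, 2, kappa = 0), "kappa")
})

test_that("well-tempered heights decay as prescribed and stay bounded", {
  kB <- 0.0019872041
  b <- bias_state()        # 0.2 kcal/mol, 0.1 A, gamma 12, 300 K
  b <- deposit_hill(b, 0.7)
  expect_equal(b$heights[1L], 0.2)
  b <- deposit_hill(b, 0.7)
  expect_equal(b$heights[2L], 0.2 * exp(-0.2 / (kB * 11 * 300)),
               tolerance = 1e-12)

  ## repeated deposits at one point: heights strictly decreasing, total
  ## bias converging to a finite limit
  n <- 10000L
  heights <- numeric(n)
  v <- 0
  kBdT <- kB * 11 * 300
  for (i in seq_len(n)) {          # all hills share one center
    h <- 0.2 * exp(-v / kBdT)
    heights[i] <- h
    v <- v + h
  }
  expect_true(all(diff(heights) < 0))
  ## V(n) = kB dT log(1 + n h0 / kB dT) for coincident hills: bounded slow
  ## growth; the last increments are tiny compared to the first
  expect_lt(heights[n] / heights[1L], 0.05)
  expect_lt(v, kBdT * log(1 + n * 0.2 / kBdT) + 0.2)

  ## the incremental deposit_hill agrees with this recursion
  b2 <- bias_state()
  for (i in 1:5) b2 <- deposit_hill(b2, -0.4)
  expect_equal(b2$heights, heights[1:5], tolerance = 1e-12)
})

test_that("bias evaluation is an exact Gaussian sum with analytic slope", {
  b <- bias_state()
  e0 <- evaluate_bias(b, 0.3)
  expect_equal(e0$energy, 0)
  expect_equal(e0$derivative, 0)

  b <- deposit_hill(b, 1.0)
  at_center <- evaluate_bias(b, 1.0)
  expect_equal(at_center$energy, 0.2)
  expect_equal(at_center$derivative, 0)
  at_sigma <- evaluate_bias(b, 1.1)
  expect_equal(at_sigma$energy, 0.2 * exp(-0.5), tolerance = 1e-12)
  expect_equal(at_sigma$derivative, -0.2 * exp(-0.5) * 0.1 / 0.01,
               tolerance = 1e-12)
})

test_that("the toy integrator is deterministic and diffuses per Einstein", {
  flat <- run_toy_metad(coefs = 0, n_steps = 2e5, diffusion = 2e-5,
                        x0 = 0, biased = FALSE, seed = 42L,
                        domain = c(-50, 50), record_stride = 10L)
  flat2 <- run_toy_metad(coefs = 0, n_steps = 2e5, diffusion = 2e-5,
                         x0 = 0, biased = FALSE, seed = 42L,
                         domain = c(-50, 50), record_stride = 10L)
  expect_identical(flat$cv, flat2$cv)

  ## time-averaged MSD at a 100 fs lag: 2 D tau within 20%
  x <- flat$cv
  lag <- 10L                       # 10 records = 100 fs
  msd <- mean((x[-(1:lag)] - x[seq_len(length(x) - lag)])^2)
  expect_lt(abs(msd - 2 * 2e-5 * 100) / (2 * 2e-5 * 100), 0.2)
})

test_that("the bias grid used by the integrator matches the exact hill sum", {
  run <- run_toy_metad(n_steps = 1e5, seed = 2L)
  g <- run$bias$gamma
  xs <- seq(-1.8, 1.8, by = 0.2)
  ## bias implied by the gridded free-energy estimate, up to a constant
  vb_grid <- sapply(xs, function(x)
    -(g - 1) / g * run$fes$F[which.min(abs(run$fes$cv - x))])
  vb_exact <- evaluate_bias(run$bias, xs)$energy
  diffs <- (vb_grid - mean(vb_grid)) - (vb_exact - mean(vb_exact))
  expect_lt(max(abs(diffs)), 2e-3)
})

test_that("biasing drives barrier crossing that unbiased dynamics lacks", {
  unbiased <- run_toy_metad(n_steps = 2e4, biased = FALSE, seed = 7L)
  expect_true(all(unbiased$cv < 0))          # stays in the starting well
  biased <- run_toy_metad(n_steps = 6e5, seed = 7L)
  expect_gt(max(biased$cv), 0.8)             # reaches the other well
  expect_gt(diff(range(biased$cv)) / diff(range(unbiased$cv)), 3)
})

test_that("trajectories escaping the domain abort with the step number", {
  ## a downhill potential pushes the walker over the wall
  expect_error(run_toy_metad(coefs = c(0, 50), n_steps = 1e5,
                             biased = FALSE, seed = 1L),
               "left the domain")
})
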