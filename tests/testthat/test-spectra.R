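test_that("velocity estimation is exact for linear tracks, O(dt^2) for smooth ones", {
  dt <- 0.5
  t <- (0:199) * dt
  lin <- cbind(0.3 * t, -0.1 * t, 0 * t)
  v <- estimate_velocity(lin, dt)
  expect_equal(v[50, ], c(0.3, -0.1, 0), tolerance = 1e-12)
  expect_equal(nrow(v), 200L)

  cst <- matrix(1.5, 10L, 3L)
  expect_equal(max(abs(estimate_velocity(cst, dt))), 0)

  om <- 2 * pi * 0.02
  sine <- cbind(sin(om * t), 0, 0)
  vs <- estimate_velocity(sine, dt)
  interior <- 2:199
  err <- max(abs(vs[interior, 1L] - om * cos(om * t[interior])))
  expect_lt(err, om^3 * dt^2 / 6 * 1.01)

  expect_error(estimate_velocity(lin[1:2, ], dt), "at least 3")
  expect_error(estimate_velocity(lin, 0), "dt")
})

test_that("the VACF has the right zero lag, decorrelation and cosine forms", {
  set.seed(10L)
  v <- matrix(rnorm(3 * 4000), ncol = 3L)
  cv <- vacf(v, 40L)
  expect_equal(cv[1L], mean(rowSums(v * v)))
  ## white noise decorrelates: |C(tau>0)| within a few sampling s.e.
  expect_lt(max(abs(cv[-1L])), 5 * sqrt(3 / 4000) * 1.5)

  t <- 0:2047
  nu <- 1 / 32
  vc <- cbind(cos(2 * pi * nu * t), 0, 0)
  cc <- vacf(vc, 64L)
  expect_equal(cc / cc[1L], cos(2 * pi * nu * 0:64), tolerance = 0.02)

  expect_error(vacf(v, 4000L), "max_lag")
})

test_that("spectral peaks land within one grid step of the input frequency", {
  for (freq in c(600, 1200, 1750, 3000)) {
    tr <- make_oscillating_track(freq, dt_fs = 0.5, n = 4096L)
    sp <- track_spectrum(tr, 0.5, window_cm = 33)
    pk <- sp$frequency[which.max(sp$intensity)]
    expect_lt(abs(pk - freq), sp$resolution + 1e-9)
  }
  ## robust to seeded noise (property over seeds)
  for (seed in 1:5) {
    tr <- make_oscillating_track(1200, noise = 0.01, seed = seed)
    sp <- track_spectrum(tr, 0.5, window_cm = 33)
    expect_lt(abs(sp$frequency[which.max(sp$intensity)] - 1200),
              sp$resolution + 1e-9)
  }
  ## two tones resolve into two maxima
  tr2 <- make_oscillating_track(c(1200, 1750), dt_fs = 0.5, n = 4096L)
  sp2 <- track_spectrum(tr2, 0.5, window_cm = 33)
  i <- sp2$intensity
  locmax <- which(diff(sign(diff(i))) == -2) + 1L
  locmax <- locmax[i[locmax] > 0.2 * max(i)]
  expect_length(locmax, 2L)
  expect_lt(abs(sp2$frequency[locmax[1L]] - 1200), 2 * sp2$resolution)
  expect_lt(abs(sp2$frequency[locmax[2L]] - 1750), 2 * sp2$resolution)
})

test_that("zero and translational motion carry no finite-frequency weight", {
  z <- ir_spectrum(matrix(0, 256L, 3L), 0.5)
  expect_equal(max(z$intensity), 0)

  tr <- cbind((0:2047) * 0.01, 0, 0)      # uniform drift
  sp <- track_spectrum(tr, 0.5, window_cm = 33)
  expect_equal(which.max(sp$intensity), 1L)
  expect_lt(sum(sp$intensity[sp$frequency > 300]) / sum(sp$intensity), 1e-9)
})

test_that("total one-sided power equals the zero-lag VACF (Parseval)", {
  set.seed(2L)
  v <- matrix(rnorm(3 * 2048), ncol = 3L)
  sp <- ir_spectrum(v, 0.5, window = "none")
  expect_lt(abs(spectrum_power(sp) - vacf(v, 0L)[1L]) / vacf(v, 0L)[1L],
            0.01)
  ## a tone aligned with the frequency grid (bin 40 of 1024) keeps the
  ## untapered transform essentially non-negative
  vel <- cbind(cos(2 * pi * 40 * (0:2047) / 2048), 0, 0)
  ## short lags keep the time-origin average well converged
  spt <- ir_spectrum(vel, 0.5, window = "none", max_lag = 256L)
  expect_lt(abs(spectrum_power(spt) - vacf(vel, 0L)[1L]) / vacf(vel, 0L)[1L],
            0.01)
})

test_that("running-average smoothing behaves like a boxcar", {
  tr <- make_oscillating_track(1200, n = 2048L)
  sp <- ir_spectrum(estimate_velocity(tr, 0.5), 0.5)

  flat <- sp
  flat$intensity <- rep(2.5, length(flat$intensity))
  expect_equal(smooth_spectrum(flat, 33)$intensity, flat$intensity)

  ## single-bin spike spreads into a plateau of height h / w
  spike <- sp
  spike$intensity <- rep(0, length(spike$intensity))
  spike$intensity[100L] <- 7
  w <- 2L * floor(130 / spike$resolution / 2) + 1L
  sm <- smooth_spectrum(spike, 130)
  expect_equal(sm$intensity[100L], 7 / w, tolerance = 1e-12)
  expect_equal(sum(sm$intensity > 0), w)

  ## window equal to the resolution is the identity
  expect_equal(smooth_spectrum(sp, sp$resolution)$intensity, sp$intensity)
  expect_error(smooth_spectrum(sp, sp$resolution / 2), "below the grid")
})

test_that("motion outside the three shells leaves the CEC spectrum empty", {
  net <- make_ideal_network()
  base <- cec_frame(c(net$elements, "O", "H", "H"),
                    rbind(net$positions,
                          c(14, 0, 0), c(14.97, 0, 0), c(13.76, 0.9, 0)))
  nfr <- 72L
  t <- (0:(nfr - 1L)) * 0.5
  frames <- lapply(seq_len(nfr), function(i) {
    f <- base
    off <- 0.05 * sin(2 * pi * (1200 / 33356.40952) * t[i])
    idx <- (base$natoms - 2L):base$natoms
    f$positions[idx, 1L] <- f$positions[idx, 1L] + off
    f$time <- t[i]
    f
  })
  series <- cec_frames(frames, dt = 0.5)
  cecs <- t(vapply(track_cec(series), `[[`, numeric(3L), "cec"))
  sp <- ir_spectrum(estimate_velocity(cecs, 0.5), 0.5)
  expect_equal(max(sp$intensity), 0)
})
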