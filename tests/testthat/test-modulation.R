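test_that("F1/F0 reproduces the closed-form cases", {
  T <- 32
  ph <- (seq_len(T) - 1) / T * 2 * pi
  # constant positive response: F1 = 0 -> complex
  mr <- modulation_ratio(rep(2, T))
  expect_equal(mr$F1, 0)
  expect_equal(mr$f1f0, 0)
  expect_equal(mr$classification, "complex")
  # 1 + cos has F1 = F0 = 1
  mr <- modulation_ratio(1 + cos(ph))
  expect_equal(mr$f1f0, 1, tolerance = 1e-12)
  # half-rectified cosine: F1/F0 -> pi/2 (the chi = 0 case)
  T2 <- 256
  ph2 <- (seq_len(T2) - 1) / T2 * 2 * pi
  mr <- modulation_ratio(pmax(cos(ph2), 0))
  expect_equal(mr$f1f0, pi / 2, tolerance = 1e-3)
  # zero curve flagged non-responsive
  expect_equal(modulation_ratio(rep(0, T))$classification, "nonresponsive")
})

test_that("the chi -> F1/F0 mapping matches its analytic anchors", {
  expect_equal(chi_to_f1f0(-1), 1)
  expect_equal(chi_to_f1f0(-2), 0.5)
  expect_equal(chi_to_f1f0(0), pi / 2, tolerance = 1e-12)
  # continuity at the branch point
  expect_lt(abs(chi_to_f1f0(-1 - 1e-13) - chi_to_f1f0(-1 + 1e-13)), 1e-12)
  # monotone decreasing in chi... the ratio rises as rectification deepens
  grid <- seq(-3, 0.9, by = 0.1)
  expect_true(all(diff(chi_to_f1f0(grid)) > 0))
  expect_error(chi_to_f1f0(1.5), "undefined")
})

test_that("measured F1/F0 on model curves agrees with the analytic mapping", {
  # the central measurement identity: curves synthesized from the
  # half-rectified sinusoid model must land on the closed-form curve
  T <- 256
  ph <- (seq_len(T) - 1) / T * 2 * pi
  for (chi in seq(-3, 0.9, by = 0.1)) {
    r <- pmax(cos(ph - 0.7) - chi, 0) # a = 1, b = chi
    measured <- modulation_ratio(r)$f1f0
    expect_equal(measured, chi_to_f1f0(chi), tolerance = 0.01)
  }
})

test_that("rectified-sine fitting recovers parameters and handles regimes", {
  T <- 64
  ph_deg <- (seq_len(T) - 1) / T * 360
  ph <- ph_deg * pi / 180
  # noisy recovery of chi = b/|a| = 0.5
  set.seed(8)
  r <- pmax(2 * cos(ph - 30 * pi / 180) - 1, 0) + rnorm(T, sd = 0.01)
  f <- fit_rectified_sine(pmax(r, 0), axis = ph_deg)
  expect_lt(abs(f$chi - 0.5), 0.05)
  expect_lt(abs(((f$phi0 - 30 + 180) %% 360) - 180), 3)
  # noiseless self-fit
  r0 <- pmax(1.5 * cos(ph - 1.1) - 0.4, 0)
  f0 <- fit_rectified_sine(r0, axis = ph_deg)
  expect_lt(f0$residual, 1e-6)
  # never-clipped regime reduces to plain cosine regression
  r2 <- 0.5 * cos(ph - 0.3) + 2 # a = 0.5, b = -2 <= -|a|
  f2 <- fit_rectified_sine(r2, axis = ph_deg)
  expect_lt(f2$chi, -1)
  expect_equal(f2$a, 0.5, tolerance = 1e-6)
  expect_equal(f2$b, -2, tolerance = 1e-6)
  expect_error(fit_rectified_sine(rep(0, T)), "all-zero")
})

test_that("HWHH measures tuning width with interpolation and wraparound", {
  T <- 36
  ax <- (seq_len(T) - 1) / T * 180
  # von-Mises-like orientation tuning centred at 90 deg
  r <- exp(-((ax - 90) / 25)^2 / 2)
  w <- hwhh(r, axis = ax)
  # analytic HWHH of the Gaussian: sigma * sqrt(2 ln 2) = 29.4 deg
  expect_lt(abs(w - 25 * sqrt(2 * log(2))), 3)
  # peak near the wrap point gives the same width
  r2 <- exp(-(pmin(abs(ax - 5), 180 - abs(ax - 5)) / 25)^2 / 2)
  expect_lt(abs(hwhh(r2, axis = ax) - w), 3)
})

test_that("idealized linear and pooled units classify as simple and complex", {
  T <- 64
  size <- 15
  even <- log_gabor_kernel(size, theta = 40, phase = 0, f0 = 0.2)
  odd <- log_gabor_kernel(size, theta = 40, phase = 90, f0 = 0.2)
  sq <- grating_sequence("drift", size, orientation = 40, frequency = 0.2,
                         samples_per_cycle = T)
  lin <- vapply(seq_len(T), function(t) max(sum(even * sq[, , t]), 0), 0)
  expect_gt(modulation_ratio(lin)$f1f0, 1) # rectified linear: simple
  pooled <- vapply(seq_len(T), function(t)
    max(max(sum(even * sq[, , t]), 0), max(sum(odd * sq[, , t]), 0)), 0)
  expect_lt(modulation_ratio(pooled)$f1f0, 1) # max over quadrature pair: complex
})

test_that("an idealized rectified Gabor's curve matches the half-rectified model", {
  T <- 64
  size <- 15
  kern <- log_gabor_kernel(size, theta = 25, phase = 0, f0 = 0.2)
  sq <- grating_sequence("drift", size, orientation = 25, frequency = 0.2,
                         samples_per_cycle = T)
  resp <- vapply(seq_len(T), function(t) max(sum(kern * sq[, , t]), 0), 0)
  f <- fit_rectified_sine(resp, axis = (seq_len(T) - 1) / T * 360)
  # a linear filter + rectification is exactly the b = 0 model
  expect_lt(f$residual / max(resp), 1e-3)
  expect_lt(abs(f$chi), 0.05)
})
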