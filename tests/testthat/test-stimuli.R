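test_that("whitening removes DC, bounds values, and imposes the ramp spectrum", {
  expect_equal(as.numeric(whiten_images(matrix(0.7, 16, 16))), rep(0, 256))
  set.seed(1)
  wn <- array(rnorm(64 * 64 * 2), dim = c(64, 64, 2))
  w <- whiten_images(wn)
  expect_true(max(abs(w)) <= 1 + 1e-12)
  expect_true(isTRUE(attr(w, "whitened")))
  # radially averaged amplitude spectrum rises ~ f below f_c/2
  sl <- sdpcv1:::spectral_slope(w[, , 1], fmax = 0.1) # f_c = 0.2, check below f_c/2
  expect_lt(abs(sl - 1), 0.2)
  expect_error(whiten_images(matrix(1, 1, 1)), "2x2")
})

test_that("whitening is idempotent up to rescaling on already-flat spectra", {
  set.seed(1)
  wn <- array(rnorm(64 * 64), dim = c(64, 64, 1)) # flat-spectrum input
  v1 <- whiten_images(wn)
  v2 <- whiten_images(array(v1, dim = dim(v1)))
  b1 <- as.numeric(v1) / sqrt(sum(v1^2))
  b2 <- as.numeric(v2) / sqrt(sum(v2^2))
  expect_gt(cor(b1, b2), 0.99)
  expect_lt(sqrt(sum((b1 - b2)^2)), 0.05) # < 5% relative change
})

test_that("gratings follow the cosine geometry and symmetries", {
  g <- make_grating(15, orientation = 0, phase = 0, frequency = 0.2,
                    mask_diameter = 14, contrast = 0.8)
  expect_equal(g[8, 8], 0.8) # centre pixel, cos(0) = 1
  expect_true(all(g[sqrt(outer((1:15) - 8, rep(0, 15), "+")^2 +
                           outer(rep(0, 15), (1:15) - 8, "+")^2) > 7] == 0))
  # 360 degree phase periodicity
  expect_equal(make_grating(15, 30, 45, 0.2), make_grating(15, 30, 405, 0.2))
  # orientation + 180 with phase negated is the same stimulus
  expect_equal(make_grating(15, 30, 45, 0.2), make_grating(15, 210, -45, 0.2),
               tolerance = 1e-12)
  expect_error(make_grating(15, frequency = 0.6), "Nyquist")
})

test_that("drift and rotation sequences sweep one cycle uniformly", {
  sq <- grating_sequence("drift", 15, orientation = 20, frequency = 0.2,
                         samples_per_cycle = 4)
  expect_equal(attr(sq, "axis"), c(0, 90, 180, 270))
  expect_equal(dim(sq)[3], 4L)
  # periodic closure: frame at phase 360 equals frame at phase 0
  closing <- make_grating(15, 20, 0 + 360, 0.2)
  expect_equal(sq[, , 1], closing)
  rq <- grating_sequence("rotate", 15, orientation = 0, frequency = 0.2,
                         samples_per_cycle = 4)
  expect_equal(attr(rq, "axis"), c(0, 45, 90, 135))
  expect_equal(attr(rq, "cycle_definition"), 180)
  # an ideal orientation-energy detector responds with a single peak
  T <- 16
  rq2 <- grating_sequence("rotate", 15, orientation = 0, frequency = 0.2,
                          samples_per_cycle = T)
  even <- log_gabor_kernel(15, theta = 60, phase = 0, f0 = 0.2)
  odd <- log_gabor_kernel(15, theta = 60, phase = 90, f0 = 0.2)
  resp <- vapply(seq_len(T), function(t)
    sum(even * rq2[, , t])^2 + sum(odd * rq2[, , t])^2, 0)
  pk <- which(resp > 0.5 * max(resp))
  expect_lt(length(pk), T / 2) # tuned, not flat
  # single contiguous peak (circular): runs of above-half samples
  runs <- rle(seq_len(T) %in% pk)
  n_runs <- sum(runs$values)
  if (runs$values[1] && runs$values[length(runs$values)]) n_runs <- n_runs - 1
  expect_equal(n_runs, 1L)
})

test_that("the synthetic image generator is seed-deterministic with ~1/f spectra", {
  a <- synthetic_images(3, 32, seed = 9)
  b <- synthetic_images(3, 32, seed = 9)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_true(max(abs(a)) <= 1)
  sl <- mean(vapply(1:3, function(i) sdpcv1:::spectral_slope(a[, , i]), 0))
  expect_lt(abs(sl - (-1)), 0.3)
  # edge orientations are uniform on [0, 180)
  big <- synthetic_images(80, 48, seed = 10)
  ed <- attr(big, "edges")
  expect_gt(nrow(ed), 500)
  h <- table(cut(ed$theta, breaks = seq(0, 180, by = 18)))
  p <- suppressWarnings(chisq.test(h)$p.value)
  expect_gt(p, 0.01)
  # whitened output respects the bound
  w <- synthetic_images(2, 24, seed = 4, whiten = TRUE)
  expect_true(isTRUE(attr(w, "whitened")))
  expect_true(max(abs(w)) <= 1)
})

test_that("the external loader degrades gracefully and crops deterministically", {
  expect_error(load_image_dataset("/nonexistent/path", 4), "synthetic_images")
  # STL-style binary fixture: two 3x96x96 uint8 records
  tmp <- tempfile(fileext = ".bin")
  set.seed(2)
  writeBin(as.raw(sample(0:255, 2 * 3 * 96 * 96, replace = TRUE)), tmp)
  b1 <- load_image_dataset(tmp, 2, size = 40, seed = 3)
  b2 <- load_image_dataset(tmp, 2, size = 40, seed = 3)
  expect_identical(as.numeric(b1), as.numeric(b2))
  expect_equal(dim(b1), c(40L, 40L, 2L))
  b96 <- load_image_dataset(tmp, 1, size = 96, seed = 3)
  expect_equal(dim(b96)[1:2], c(96L, 96L))
  b0 <- load_image_dataset(tmp, 0, size = 32)
  expect_equal(dim(b0)[3], 0L)
  unlink(tmp)
})
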