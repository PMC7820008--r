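test_that("triplet derivative is exact on quadratics and linear functions", {
  f <- 1:10
  expect_equal(triplet_derivative(f^2, 1), 2 * (2:9), tolerance = 1e-12)
  expect_equal(triplet_derivative(3 * f + 1, 1), rep(3, 8), tolerance = 1e-12)
  # general quadratics, non-unit step
  set.seed(5)
  for (i in 1:10) {
    a <- runif(1, -3, 3); b <- runif(1, -3, 3); c0 <- runif(1, -3, 3)
    h <- runif(1, 0.1, 2)
    x <- seq(0, by = h, length.out = 12)
    d <- triplet_derivative(a * x^2 + b * x + c0, h)
    expect_equal(d, 2 * a * x[2:11] + b, tolerance = 1e-12)
  }
  expect_error(triplet_derivative(c(1, 2), 1), "3 points")
})

test_that("triplet derivative of sin meets the Taylor error bound", {
  h <- 0.25
  x <- seq(0, 10, by = h)
  d <- triplet_derivative(sin(x), h)
  err <- max(abs(d - cos(x[2:(length(x) - 1)])))
  expect_lt(err, h^2 / 6)
})

test_that("a single Gaussian bump yields one peak at the closed-form maximizer", {
  b <- bump(13, 0.8, 0.5)
  sp <- model_spectrum(lnC = 5, alpha = -2.5, bumps = b)
  fit <- powerlaw_fit(sp)
  pk <- detect_peaks(sp, fit)
  expect_equal(nrow(pk), 1)
  oracle <- dense_peak_oracle(5, -2.5, b)
  expect_lt(abs(pk$freq - oracle$freq), 0.02)
  expect_lt(abs(pk$whitened_amp - oracle$whitened) / oracle$whitened, 0.02)
})

test_that("two bumps are both found and ranked by whitened amplitude", {
  b <- rbind(bump(11.5, 0.8, 0.5), bump(14, 0.4, 0.5))
  sp <- model_spectrum(lnC = 5, alpha = -2.5, bumps = b)
  pk <- detect_peaks(sp, powerlaw_fit(sp))
  expect_equal(nrow(pk), 2)
  expect_equal(pk$rank, c(1L, 2L))
  oracle <- dense_peak_oracle(5, -2.5, b)
  expect_lt(abs(pk$freq[1] - oracle$all$freq[1]), 0.02)
  expect_lt(abs(pk$freq[2] - oracle$all$freq[2]), 0.02)
  # background tilt displaces maxima slightly below the bump centers
  expect_lt(abs(pk$freq[1] - 11.5), 0.1)
  expect_lt(abs(pk$freq[2] - 14), 0.2)
  expect_true(pk$whitened_amp[1] >= pk$whitened_amp[2])
})

test_that("monotone spectra and out-of-band bumps give zero peaks", {
  sp <- model_spectrum(lnC = 5, alpha = -2.5)
  expect_equal(nrow(detect_peaks(sp, powerlaw_fit(sp))), 0)

  # bump at 7 Hz: inside the fit exclusion band, outside the 9-18 search band
  # (narrow width so the Gaussian tail is below machine precision at 6 Hz)
  sp7 <- model_spectrum(lnC = 5, alpha = -2.5, bumps = bump(7, 0.8, 0.12))
  fit7 <- powerlaw_fit(sp7)
  expect_lt(abs(fit7$alpha + 2.5), 1e-9)
  expect_equal(nrow(detect_peaks(sp7, fit7)), 0)

  res <- find_spindle_peaks(sp)
  expect_true(is.na(res$f_maxPeak) && is.na(res$lnPPeak))
  expect_equal(res$n_peaks, 0L)
})

test_that("whitening subtracts the background exactly", {
  sp <- model_spectrum(lnC = 5, alpha = -2.5)
  fit <- powerlaw_fit(sp)
  q <- c(3, 9.5, 13, 25, 47)
  expect_equal(whiten_at(sp, fit, q), rep(0, 5), tolerance = 1e-6)

  b <- bump(13, 0.6, 0.5)
  spb <- model_spectrum(lnC = 5, alpha = -2.5, bumps = b)
  expect_equal(whiten_at(spb, powerlaw_fit(spb), 13), 0.6, tolerance = 1e-6)
  expect_error(whiten_at(sp, fit, 1000), "outside")
})

test_that("whitened amplitude is gauge-invariant under global power scaling", {
  b <- bump(12.5, 0.7, 0.6)
  sp <- model_spectrum(lnC = 5, alpha = -2.5, bumps = b)
  sp2 <- sp; sp2$power <- sp2$power * exp(1.3)  # +1.3 on the ln P axis
  f1 <- powerlaw_fit(sp); f2 <- powerlaw_fit(sp2)
  expect_equal(f2$lnC0 - f1$lnC0, 1.3, tolerance = 1e-9)
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-9)
  p1 <- detect_peaks(sp, f1); p2 <- detect_peaks(sp2, f2)
  expect_equal(p2$freq, p1$freq, tolerance = 1e-7)
  expect_equal(p2$whitened_amp, p1$whitened_amp, tolerance = 1e-7)
})

test_that("peak localization sweep stays within tolerance across the band", {
  # well-conditioned bumps: the local maximum clearly exists, so the
  # quadratic-triplet chain localizes within its O(h^2) truncation error
  set.seed(9)
  for (i in 1:20) {
    b <- bump(runif(1, 10.5, 16.5), runif(1, 0.5, 1.0), runif(1, 0.35, 0.8))
    sp <- model_spectrum(lnC = 5, alpha = -2.5, bumps = b)
    pk <- detect_peaks(sp, powerlaw_fit(sp))
    oracle <- dense_peak_oracle(5, -2.5, b)
    expect_gte(nrow(pk), 1)
    expect_lt(abs(pk$freq[1] - oracle$freq), 0.02)
    expect_lt(abs(pk$whitened_amp[1] - oracle$whitened) / oracle$whitened, 0.02)
  }
})

test_that("bumps too shallow to produce a local maximum yield no peak", {
  # height/width combination where the background slope dominates the bump
  # gradient everywhere: the generating curve is monotone within the band
  b <- bump(13.5, 0.2, 1.0)
  expect_null(dense_peak_oracle(5, -2.5, b))
  sp <- model_spectrum(lnC = 5, alpha = -2.5, bumps = b)
  expect_equal(nrow(detect_peaks(sp, powerlaw_fit(sp))), 0)
})
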