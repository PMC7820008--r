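test_that("window selection enumerates 2 s-hop windows inside staged, clean data", {
  rec <- noise_recording(duration_s = 90, sfreq = 100)
  rec$epoch_stages <- rep("N2", 5)  # 100 s scored covers the 90 s signal
  starts <- select_windows(rec)
  expect_equal(starts, seq(0, 86, by = 2))  # 44 windows

  rec$artifact_mask[11] <- TRUE  # [40, 44) s
  starts <- select_windows(rec)
  expect_length(starts, 41)
  expect_false(any(starts %in% c(38, 40, 42)))

  rec$epoch_stages <- rep("W", 5)
  expect_error(select_windows(rec), "no artifact-free NREM data")
})

test_that("windows stop at stage boundaries out of the accepted set", {
  rec <- noise_recording(duration_s = 100, sfreq = 100)
  rec$epoch_stages <- c("N2", "N2", "W", "N3", "N3")
  starts <- select_windows(rec)
  # [36, 40) is the last window of the first N2 block; nothing may touch [40, 60)
  expect_true(all(starts + 4 <= 40 | starts >= 60))
  expect_true(36 %in% starts && 60 %in% starts)
})

test_that("averaged periodogram localizes a sinusoid and conserves variance", {
  sfreq <- 100
  t <- (0:(600 * sfreq - 1)) / sfreq
  sine <- sqrt(2) * sin(2 * pi * 10 * t)  # unit variance
  starts <- seq(0, 596, by = 2)
  sp <- average_periodogram(sine, sfreq, starts, channel = "C3")
  expect_equal(sp$frequency[which.max(sp$power)], 10)
  expect_equal(sp$frequency, seq(0, 50, by = 0.25))
  expect_equal(unique(sp$n_windows), length(starts))

  set.seed(11)
  wn <- rnorm(600 * sfreq, 0, 2)
  spw <- average_periodogram(wn, sfreq, starts)
  integral <- sum(spw$power[-1]) * 0.25
  expect_lt(abs(integral - 4) / 4, 0.05)  # Parseval within 5%

  # DC signal: all energy at 0 Hz up to Hann-taper leakage into adjacent bins
  dc <- average_periodogram(rep(3, 1000), sfreq, 0)
  expect_equal(dc$frequency[which.max(dc$power)], 0)
  expect_lt(max(dc$power[dc$frequency > 1]), 1e-6 * dc$power[1])
})

test_that("PSD scales quadratically with amplitude and supports odd rates", {
  set.seed(12)
  x <- rnorm(249 * 60)
  starts <- seq(0, 50, by = 2)
  a <- average_periodogram(x, 249, starts)       # 996-sample windows
  b <- average_periodogram(3 * x, 249, starts)
  expect_equal(a$frequency, seq(0, 124.5, by = 0.25))
  expect_equal(b$power, 9 * a$power, tolerance = 1e-12)
  expect_error(average_periodogram(x, 249, 100), "bounds")
})

test_that("calibration averages the two amplitude conditions and inverts exactly", {
  anchors <- c(0.5, 1, 2, 5, 10, 20, 50)
  cal <- build_calibration(anchors, rep(0.8, 7), rep(1.0, 7))
  expect_equal(calibration_rate(cal, anchors), rep(0.9, 7), tolerance = 1e-12)
  # clamped outside the anchor span
  expect_equal(calibration_rate(cal, c(0.1, 100)), c(0.9, 0.9))

  flat <- build_calibration(anchors, rep(1, 7), rep(1, 7))
  expect_equal(calibration_rate(flat, seq(0.5, 50, 0.7)),
               rep(1, length(seq(0.5, 50, 0.7))), tolerance = 1e-12)

  expect_error(build_calibration(c(1, 2, 3), rep(1, 3), rep(1, 3)), "4 anchor")

  sp <- model_spectrum()
  rates40 <- seq(0.6, 1.0, length.out = 9)
  cal2 <- build_calibration(seq(0.5, 60, length.out = 9), rates40, rates40)
  corrected <- apply_calibration(sp, cal2)
  rate <- calibration_rate(cal2, sp$frequency)
  # stated formula: division by the squared reduction rate, hence invertible
  expect_equal(corrected$power * rate^2, sp$power, tolerance = 1e-12)
  at_anchor <- which(sp$frequency == 0.5)
  expect_equal(corrected$power[at_anchor], sp$power[at_anchor] / 0.6^2,
               tolerance = 1e-9)
})

test_that("compute_spectra runs the full per-channel pipeline", {
  rec <- noise_recording(duration_s = 120, sfreq = 100,
                         channels = c("C3", "O1"))
  sp <- compute_spectra(rec)
  expect_setequal(unique(sp$channel), c("C3", "O1"))
  expect_equal(nrow(sp), 2 * (2 * 100 + 1))
  expect_true(all(sp$power >= 0))
})
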