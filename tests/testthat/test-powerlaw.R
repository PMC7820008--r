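test_that("equidistant log-log grid uses the smallest source log-step", {
  sp <- model_spectrum()
  ll <- to_equidistant_loglog(sp)
  step <- log(48) - log(47.75)
  expect_equal(ll$step, step, tolerance = 1e-12)
  expect_equal(round(ll$step, 4), 0.0052)
  expect_length(ll$lnf, floor((log(48) - log(2)) / step) + 1)
  expect_equal(diff(ll$lnf), rep(ll$step, length(ll$lnf) - 1), tolerance = 1e-12)

  # PCHIP reproduces the source knots exactly
  knots <- sp$frequency[sp$frequency >= 2 & sp$frequency <= 48]
  at_knots <- pracma::pchip(log(knots),
                            log(sp$power[match(knots, sp$frequency)]),
                            log(knots))
  expect_equal(at_knots, log(sp$power[match(knots, sp$frequency)]),
               tolerance = 1e-12)

  sp$power[sp$frequency == 10] <- 0
  expect_error(to_equidistant_loglog(sp), "10.00 Hz")
})

test_that("noiseless power-law spectra are recovered exactly", {
  for (alpha in c(-1, -2.5, -4)) {
    for (lnC in c(-2, 5)) {
      fit <- powerlaw_fit(model_spectrum(lnC = lnC, alpha = alpha))
      expect_lt(abs(fit$alpha - alpha), 1e-9)
      expect_lt(abs(fit$lnC0 - lnC), 1e-9)
      expect_equal(fit$r2, 1, tolerance = 1e-9)
    }
  }
})

test_that("alternative intercepts lie exactly on the fitted line", {
  fit <- powerlaw_fit(model_spectrum(lnC = 4, alpha = -2))
  expect_equal(unname(fit$alt_intercepts["2.5"]), 4 - 2 * 2.5, tolerance = 1e-9)
  expect_equal(evaluate_background(fit, 0), fit$lnC0)
  anchors <- c(2, 2.3, 2.5, 2.6, 2.7, 3)
  expect_equal(unname(fit$alt_intercepts), fit$lnC0 + fit$alpha * anchors)
  # linearity between any two anchors
  expect_equal(unname(fit$alt_intercepts["3.0"] - fit$alt_intercepts["2.0"]),
               fit$alpha * 1, tolerance = 1e-12)
  # the 2.5 anchor is the 12.2 Hz frequency
  expect_equal(round(exp(2.5), 1), 12.2)
  expect_equal(round(exp(2.6), 1), 13.5)
})

test_that("perturbations inside the excluded band do not move the fit", {
  base <- powerlaw_fit(model_spectrum(lnC = 5, alpha = -2.5))
  bumped <- powerlaw_fit(model_spectrum(
    lnC = 5, alpha = -2.5, bumps = bump(13, 0.8, 0.5)))
  expect_lt(abs(bumped$alpha - base$alpha), 1e-9)
  expect_lt(abs(bumped$lnC0 - base$lnC0), 1e-9)

  # arbitrary bounded perturbation inside the excluded band, clear of the
  # boundary knots that the PCHIP interpolation stencil still reaches
  sp <- model_spectrum(lnC = 5, alpha = -2.5)
  inside <- sp$frequency > 6.45 & sp$frequency < 17.3
  set.seed(7)
  sp$power[inside] <- sp$power[inside] * exp(runif(sum(inside), -1, 1))
  pert <- powerlaw_fit(sp)
  expect_lt(abs(pert$alpha - base$alpha), 1e-9)
  expect_lt(abs(pert$lnC0 - base$lnC0), 1e-9)
})

test_that("slope estimate is unbiased under log-power noise and r2 decreases with it", {
  set.seed(21)
  errs <- replicate(20, {
    sp <- synth_spectrum(lnC = 5, alpha = -2.5, noise_sd = 0.05)
    powerlaw_fit(sp)$alpha - (-2.5)
  })
  expect_lt(abs(mean(errs)), 0.01)

  r2s <- vapply(c(0.02, 0.1, 0.4), function(sdv) {
    mean(replicate(5, powerlaw_fit(
      synth_spectrum(lnC = 5, alpha = -2.5, noise_sd = sdv))$r2))
  }, 0)
  expect_true(all(diff(r2s) < 0))
})

test_that("fit_background is the per-channel tidy wrapper", {
  sp <- dplyr::bind_rows(
    model_spectrum(lnC = 5, alpha = -2.5, channel = "C3"),
    model_spectrum(lnC = 4, alpha = -1.8, channel = "O1"))
  fits <- fit_background(sp)
  expect_equal(nrow(fits), 2)
  expect_equal(fits$alpha[fits$channel == "O1"], -1.8, tolerance = 1e-9)
  expect_true(all(c("lnC_2.5", "lnC_2.6", "r2") %in% names(fits)))

  td <- tidy(powerlaw_fit(model_spectrum()))
  expect_equal(td$term[1:2], c("alpha", "lnC0"))
})

test_that("slope-free pivot is located where intercepts decouple from slopes", {
  set.seed(31)
  n <- 300
  alpha <- rnorm(n, -2.5, 0.3)
  u <- rnorm(n, -1.5, 0.5)          # independent of alpha by construction
  lnC0 <- u - alpha * 2.5
  anchors <- c(2, 2.3, 2.5, 2.6, 2.7, 3)
  fits <- tibble::tibble(alpha = alpha)
  for (a in anchors) {
    fits[[paste0("lnC_", formatC(a, format = "f", digits = 1))]] <-
      lnC0 + alpha * a
  }
  piv <- slope_free_pivot(fits)
  expect_equal(attr(piv, "pivot"), 2.5)
  # below the pivot: steeper slopes mean higher intercepts (negative r)
  expect_lt(piv$r[piv$anchor_lnf == 2], 0)
  expect_gt(piv$r[piv$anchor_lnf == 3], 0)
  expect_equal(attr(piv, "sign_change")[2] >= 2.5, TRUE)
  expect_false(attr(piv, "flat_profile"))

  expect_error(slope_free_pivot(fits[1:5, ]), "10 subjects")
  fits$alpha <- -2.5
  expect_error(slope_free_pivot(fits), "constant")
})
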