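ALT_ANCHORS <- c(2, 2.3, 2.5, 2.6, 2.7, 3)

#' Resample a spectrum onto an equidistant log-log grid
#'
#' The 0.25 Hz grid is non-uniform in log frequency, which would bias a
#' log-log linear fit against low frequencies.  The spectrum is therefore
#' resampled, by monotone piecewise-cubic Hermite (PCHIP) interpolation of
#' (ln f, ln P), onto an equidistant ln-f grid whose step equals the
#' smallest consecutive log-spacing of the source grid inside
#' `[fmin, fmax]` (0.00522 ln-Hz for the default 2-48 Hz range, the
#' "0.0052" step).
#'
#' @param spectrum Tibble with `frequency`, `power` for one channel.
#' @param fmin,fmax Fit range bounds in Hz (defaults 2 and 48).
#' @return A list of class `nrem_loglog`: `lnf`, `lnp`, `step`,
#'   `source_range`.
#' @export
to_equidistant_loglog <- function(spectrum, fmin = 2, fmax = 48) {
  f <- spectrum$frequency
  p <- spectrum$power
  in_range <- f >= fmin & f <= fmax
  if (!any(f <= fmin) || !any(f >= fmax)) {
    abort(sprintf("spectrum grid does not cover [%g, %g] Hz", fmin, fmax))
  }
  if (any(p[in_range] <= 0)) {
    bad <- f[in_range][which(p[in_range] <= 0)[1]]
    abort(sprintf("non-positive power at %.2f Hz; log undefined", bad))
  }
  fs <- f[in_range]
  step <- min(diff(log(fs)))
  n_pts <- floor((log(fmax) - log(fmin)) / step) + 1
  lnf <- log(fmin) + step * (0:(n_pts - 1))
  lnp <- pracma::pchip(log(fs), log(p[in_range]), lnf)
  structure(
    list(lnf = lnf, lnp = lnp, step = step, source_range = c(fmin, fmax)),
    class = "nrem_loglog"
  )
}

#' Fit the power-law background of one spectrum
#'
#' Ordinary least squares of ln P on ln f over the equidistant log-log grid,
#' excluding the closed band `exclude` (defaults to 6.0052-17.9948 Hz, the
#' alpha and spindle bands).  The slope is the spectral exponent `alpha`,
#' the intercept at ln f = 0 is `lnC0`; alternative intercepts are the
#' fitted line evaluated at ln f = 2, 2.3, 2.5, 2.6, 2.7 and 3 (7.4, 10,
#' 12.2, 13.5, 15 and 20 Hz).  R^2 is the squared Pearson correlation
#' between fitted and observed included points.
#'
#' @param spectrum One-channel spectra tibble, or an `nrem_loglog`.
#' @param fmin,fmax Fit range in Hz.
#' @param exclude Closed frequency interval (Hz) excluded from the fit.
#' @return An object of class `powerlaw_fit` with elements `alpha`, `lnC0`,
#'   `r2`, `alt_intercepts`, `excluded_band`, `grid_step`, `channel`.
#' @export
powerlaw_fit <- function(spectrum, fmin = 2, fmax = 48,
                         exclude = c(6.0052, 17.9948)) {
  ll <- if (inherits(spectrum, "nrem_loglog")) {
    spectrum
  } else {
    to_equidistant_loglog(spectrum, fmin, fmax)
  }
  f_hz <- exp(ll$lnf)
  include <- f_hz < exclude[1] | f_hz > exclude[2]
  if (sum(include) < 10) {
    abort("fewer than 10 grid points outside the excluded band")
  }
  x <- ll$lnf[include]
  y <- ll$lnp[include]
  if (diff(range(x)) < .Machine$double.eps^0.5) {
    abort("degenerate design: all log-frequencies equal")
  }
  xc <- x - mean(x)
  alpha <- sum(xc * y) / sum(xc^2)
  lnC0 <- mean(y) - alpha * mean(x)
  fitted <- lnC0 + alpha * x
  r2 <- if (var(y) < 1e-300) 1 else suppressWarnings(cor(fitted, y)^2)
  if (is.na(r2)) r2 <- 1  # perfectly linear input: zero residual variance
  alt <- lnC0 + alpha * ALT_ANCHORS
  names(alt) <- formatC(ALT_ANCHORS, format = "f", digits = 1)
  structure(
    list(
      channel = if (!is.null(spectrum$channel)) spectrum$channel[1] else NA_character_,
      alpha = alpha, lnC0 = lnC0, r2 = r2,
      alt_intercepts = alt,
      excluded_band = exclude,
      fit_range = c(fmin, fmax),
      grid_step = ll$step
    ),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit%s> alpha = %.4f, lnC0 = %.4f, R2 = %.5f\n",
              if (is.na(x$channel)) "" else paste0(" ", x$channel),
              x$alpha, x$lnC0, x$r2))
  invisible(x)
}

#' Evaluate the fitted power-law background
#'
#' Returns `lnC0 + alpha * lnf` -- the colored-noise part of the model with
#' the peak term omitted.  Evaluating at ln f = 2.5 or 2.6 yields the
#' slope-free alternative intercepts at 12.2 and 13.5 Hz.
#'
#' @param fit A `powerlaw_fit`.
#' @param lnf Natural-log frequency values.
#' @return Background ln-power at `lnf`.
#' @export
evaluate_background <- function(fit, lnf) {
  stopifnot(inherits(fit, "powerlaw_fit"), all(is.finite(lnf)))
  fit$lnC0 + fit$alpha * lnf
}

#' @rdname powerlaw_fit
#' @param x A `powerlaw_fit`.
#' @param ... Unused.
#' @method tidy powerlaw_fit
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "lnC0", paste0("lnC_", names(x$alt_intercepts))),
    estimate = c(x$alpha, x$lnC0, unname(x$alt_intercepts))
  )
}

#' @rdname powerlaw_fit
#' @method glance powerlaw_fit
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble::tibble(
    channel = x$channel, alpha = x$alpha, lnC0 = x$lnC0, r2 = x$r2,
    grid_step = x$grid_step,
    exclude_lo = x$excluded_band[1], exclude_hi = x$excluded_band[2]
  )
}

#' Fit power-law backgrounds for every channel of a spectra table
#'
#' Data-frame-first wrapper around [powerlaw_fit()]: one row per channel
#' with slope, intercepts, alternative intercepts and goodness of fit.
#'
#' @param spectra Tidy spectra tibble (`channel`, `frequency`, `power`).
#' @param fmin,fmax,exclude See [powerlaw_fit()].
#' @return Tibble with columns `channel`, `alpha`, `lnC0`,
#'   `lnC_2.0` ... `lnC_3.0`, `r2`, `grid_step`.
#' @export
fit_background <- function(spectra, fmin = 2, fmax = 48,
                           exclude = c(6.0052, 17.9948)) {
  purrr::map_dfr(split(spectra, spectra$channel), function(df) {
    fit <- powerlaw_fit(df, fmin, fmax, exclude)
    row <- tibble::tibble(channel = df$channel[1],
                          alpha = fit$alpha, lnC0 = fit$lnC0)
    for (nm in names(fit$alt_intercepts)) {
      row[[paste0("lnC_", nm)]] <- unname(fit$alt_intercepts[nm])
    }
    row$r2 <- fit$r2
    row$grid_step <- fit$grid_step
    row
  })
}

#' Find the slope-free alternative intercept across subjects
#'
#' For each candidate anchor x (ln f), correlates the spectral exponent
#' `alpha` with the alternative intercept `lnC_x` across subjects; the
#' pivot is the anchor minimizing the absolute correlation.  Anchors below
#' the pivot typically correlate negatively with the slope (steeper slope,
#' higher low-frequency intercept) and anchors above positively.
#'
#' @param fits Tibble with one row per subject (or subject x channel
#'   aggregated) carrying `alpha` and `lnC_<anchor>` columns, as produced
#'   by [fit_background()].
#' @param anchors Candidate ln-f anchors (default 2, 2.3, 2.5, 2.6, 2.7, 3).
#' @return Tibble with columns `anchor_lnf`, `anchor_hz`, `r` and attributes
#'   `pivot` (anchor with minimal |r|), `sign_change` (interval where r
#'   crosses zero, if any) and `flat_profile` flag (all |r| < 0.1).
#' @export
slope_free_pivot <- function(fits, anchors = ALT_ANCHORS) {
  if (nrow(fits) < 10) abort("at least 10 subjects are required")
  if (sd(fits$alpha) < .Machine$double.eps^0.5) {
    abort("alpha is constant across subjects; correlation undefined")
  }
  cols <- paste0("lnC_", formatC(anchors, format = "f", digits = 1))
  miss <- setdiff(cols, names(fits))
  if (length(miss)) {
    abort(paste0("missing intercept column(s): ", paste(miss, collapse = ", ")))
  }
  r <- vapply(cols, function(cl) cor(fits$alpha, fits[[cl]],
                                     use = "complete.obs"), 0)
  out <- tibble::tibble(anchor_lnf = anchors, anchor_hz = exp(anchors),
                        r = unname(r))
  pivot <- anchors[which.min(abs(r))]
  sgn <- sign(r)
  chg <- which(diff(sgn) != 0)
  attr(out, "pivot") <- pivot
  attr(out, "sign_change") <- if (length(chg)) {
    c(anchors[chg[1]], anchors[chg[1] + 1])
  } else {
    NULL
  }
  attr(out, "flat_profile") <- all(abs(r) < 0.1)
  out
}
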