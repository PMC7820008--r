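#' Triplet-parabola derivative of a uniformly sampled series
#'
#' Fits the exact second-degree polynomial through each set of three
#' successive samples (overlap of two samples, i.e. a one-sample hop) and
#' returns its derivative `2 a f + b` evaluated at the middle sample.  For
#' a uniform grid this closed form equals the central difference
#' `(y[i+1] - y[i-1]) / (2 h)` and is exact on quadratics.
#'
#' @param y Values on a uniform grid (length >= 3).
#' @param h Grid step.
#' @return Numeric vector of length `length(y) - 2` (interior points).
#' @export
triplet_derivative <- function(y, h) {
  n <- length(y)
  if (n < 3) abort("at least 3 points are required")
  if (length(h) != 1 || !is.finite(h) || h <= 0) {
    abort("h must be a single positive grid step")
  }
  (y[3:n] - y[1:(n - 2)]) / (2 * h)
}

# natural-cubic-spline zero crossings of (x, y), restricted to [lo, hi];
# brackets from sample sign changes, refined by bisection to tol
spline_roots <- function(x, y, lo = min(x), hi = max(x), tol = 1e-9) {
  sf <- splinefun(x, y, method = "natural")
  s <- sign(y)
  roots <- numeric(0)
  # exact zeros at samples
  roots <- c(roots, x[s == 0])
  idx <- which(s[-length(s)] * s[-1] < 0)
  for (i in idx) {
    a <- x[i]; b <- x[i + 1]
    fa <- sf(a)
    while (b - a > tol) {
      m <- (a + b) / 2
      fm <- sf(m)
      if (fm == 0) { a <- m; b <- m; break }
      if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else b <- m
    }
    roots <- c(roots, (a + b) / 2)
  }
  sort(roots[roots >= lo & roots <= hi])
}

#' Whitened ln-power at a query frequency
#'
#' Spline-interpolates ln P at `f_query` in the log-log plane and subtracts
#' the fitted power-law background `lnC0 + alpha * ln f`.  On a spectrum
#' equal to its background the result is zero everywhere; a spectral bump
#' of height b (in ln-power) yields b.
#'
#' @param spectrum One-channel spectra tibble.
#' @param fit A `powerlaw_fit` for the same channel.
#' @param f_query Frequencies in Hz (inside the spectrum's positive range).
#' @param shift Optional positive constant added to power before taking
#'   logs (compatibility option; default 0, the pure subtraction).
#' @return Whitened amplitude(s) in ln-power units.
#' @export
whiten_at <- function(spectrum, fit, f_query, shift = 0) {
  f <- spectrum$frequency
  p <- spectrum$power + shift
  pos <- f > 0 & p > 0
  if (any(f_query < min(f[pos])) || any(f_query > max(f[pos]))) {
    abort("query frequency outside the spectrum's usable range")
  }
  sf <- splinefun(log(f[pos]), log(p[pos]), method = "natural")
  sf(log(f_query)) - evaluate_background(fit, log(f_query))
}

#' Detect whitened spectral peaks in the spindle band
#'
#' Local maxima of ln P over the 9-18 Hz band are found by the first and
#' second derivative tests: both derivative series come from exact
#' quadratic fits over successive 0.25 Hz bin triplets
#' ([triplet_derivative()]; the second series takes the first as input),
#' zero crossings of the spline-interpolated first derivative are located
#' by bisection, the spline-interpolated second derivative is evaluated at
#' each crossing, and crossings with P' = 0 and P'' < 0 are accepted.
#' Accepted peaks are quantified by their whitened amplitude
#' ([whiten_at()]) and ranked (rank 1 = largest; ties broken toward the
#' lower frequency).  Peaks are only sought where both derivative splines
#' interpolate, i.e. within two bins of the band edges.
#'
#' @param spectrum One-channel spectra tibble covering the band.
#' @param fit A `powerlaw_fit` used for whitening.
#' @param band Search band in Hz (default `c(9, 18)`).
#' @return Tibble of class `nrem_peaks` with columns `channel`, `rank`,
#'   `freq`, `whitened_amp`, `n_detected`; zero rows when no peak is found
#'   (missing-data semantics downstream).
#' @export
detect_peaks <- function(spectrum, fit, band = c(9, 18)) {
  f <- spectrum$frequency
  sel <- f >= band[1] & f <= band[2]
  if (min(f) > band[1] || max(f) < band[2]) {
    abort(sprintf("spectrum does not cover the %g-%g Hz band", band[1], band[2]))
  }
  fb <- f[sel]
  h <- fb[2] - fb[1]
  lnp <- log(spectrum$power[sel])

  d1 <- triplet_derivative(lnp, h)        # defined on fb[2..n-1]
  f1 <- fb[2:(length(fb) - 1)]
  d2 <- triplet_derivative(d1, h)         # defined on fb[3..n-2]
  f2 <- f1[2:(length(f1) - 1)]

  roots <- spline_roots(f1, d1, lo = min(f2), hi = max(f2))
  if (length(roots) == 0) return(empty_peaks(spectrum$channel[1]))

  s2 <- splinefun(f2, d2, method = "natural")
  maxima <- roots[s2(roots) < 0]
  if (length(maxima) == 0) return(empty_peaks(spectrum$channel[1]))

  amp <- whiten_at(spectrum, fit, maxima)
  ord <- order(-amp, maxima)
  out <- tibble::tibble(
    channel = spectrum$channel[1] %||% NA_character_,
    rank = seq_along(maxima),
    freq = maxima[ord],
    whitened_amp = amp[ord],
    n_detected = length(maxima)
  )
  class(out) <- unique(c("nrem_peaks", class(out)))
  out
}

empty_peaks <- function(channel) {
  out <- tibble::tibble(
    channel = character(0), rank = integer(0), freq = numeric(0),
    whitened_amp = numeric(0), n_detected = integer(0)
  )
  class(out) <- unique(c("nrem_peaks", class(out)))
  out
}

#' Detect spindle-band peaks for every channel of a spectra table
#'
#' Data-frame-first wrapper: runs [powerlaw_fit()] (unless fits are
#' supplied) and [detect_peaks()] per channel, and summarizes the maximal
#' peak.  Channels with no accepted peak appear with `NA` `f_maxPeak` and
#' `lnPPeak` (missing data).
#'
#' @param spectra Tidy spectra tibble.
#' @param fits Optional tibble from [fit_background()]; computed if absent.
#' @param band Search band in Hz.
#' @param all_peaks If `TRUE`, return every ranked peak; otherwise one row
#'   per channel with the maximal peak.
#' @return Tibble with `channel`, `f_maxPeak`, `lnPPeak`, `n_peaks`
#'   (or ranked long form when `all_peaks = TRUE`).
#' @export
find_spindle_peaks <- function(spectra, fits = NULL, band = c(9, 18),
                               all_peaks = FALSE) {
  by_ch <- split(spectra, spectra$channel)
  rows <- purrr::map(names(by_ch), function(ch) {
    df <- by_ch[[ch]]
    fit <- if (is.null(fits)) {
      powerlaw_fit(df)
    } else {
      frow <- fits[fits$channel == ch, ]
      if (nrow(frow) == 0) abort(paste0("no background fit for channel ", ch))
      fit_from_row(frow)
    }
    pk <- detect_peaks(df, fit, band)
    if (all_peaks) return(pk)
    if (nrow(pk) == 0) {
      tibble::tibble(channel = ch, f_maxPeak = NA_real_,
                     lnPPeak = NA_real_, n_peaks = 0L)
    } else {
      tibble::tibble(channel = ch, f_maxPeak = pk$freq[1],
                     lnPPeak = pk$whitened_amp[1], n_peaks = pk$n_detected[1])
    }
  })
  dplyr::bind_rows(rows)
}

# rebuild a powerlaw_fit object from one row of fit_background() output
fit_from_row <- function(row) {
  alt <- unlist(row[grep("^lnC_", names(row))])
  names(alt) <- sub("^lnC_", "", names(alt))
  structure(
    list(channel = row$channel, alpha = row$alpha, lnC0 = row$lnC0,
         r2 = row$r2, alt_intercepts = alt,
         excluded_band = c(6.0052, 17.9948), fit_range = c(2, 48),
         grid_step = row$grid_step %||% NA_real_),
    class = "powerlaw_fit"
  )
}
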