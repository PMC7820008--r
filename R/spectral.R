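#' Select artifact-free NREM analysis windows
#'
#' Enumerates 4 s window start times (50%% overlap, i.e. a 2 s hop) that lie
#' entirely inside scoring epochs of the requested stages and intersect no
#' artifact-marked 4 s segment.  Windows may span adjacent epochs scored in
#' the same accepted stage set.
#'
#' @param recording An `nrem_recording` (see [read_recording()]).
#' @param stages Accepted stage codes; default `c("N2", "N3")` (NREM).
#' @param window_s Window length in seconds (default 4, giving 0.25 Hz bins).
#' @param overlap Fractional overlap between consecutive windows (default 0.5).
#' @return Numeric vector of window start times in seconds.
#' @export
select_windows <- function(recording, stages = c("N2", "N3"),
                           window_s = 4, overlap = 0.5) {
  stopifnot(length(stages) >= 1)
  sfreq <- recording$sfreq
  if ((window_s * sfreq) %% 1 != 0) {
    abort("window_s x sfreq must be an integer number of samples")
  }
  hop <- window_s * (1 - overlap)
  duration <- length(recording$signals[[1]]) / sfreq
  starts <- seq(0, duration - window_s, by = hop)
  if (length(starts) == 0) abort("no artifact-free NREM data")

  ep_len <- recording$epoch_length_s
  ep_ok <- recording$epoch_stages %in% stages
  n_ep <- length(ep_ok)

  keep <- vapply(starts, function(t0) {
    # epochs overlapped by [t0, t0 + window_s)
    e_lo <- floor(t0 / ep_len) + 1
    e_hi <- ceiling((t0 + window_s) / ep_len)
    if (e_hi > n_ep) return(FALSE)
    if (!all(ep_ok[e_lo:e_hi])) return(FALSE)
    # 4 s artifact segments overlapped by the window
    s_lo <- floor(t0 / 4) + 1
    s_hi <- ceiling((t0 + window_s) / 4)
    s_hi <- min(s_hi, length(recording$artifact_mask))
    !any(recording$artifact_mask[s_lo:s_hi])
  }, logical(1))

  out <- starts[keep]
  if (length(out) == 0) abort("no artifact-free NREM data")
  out
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

#' Averaged Hann-tapered periodogram
#'
#' One-sided power spectral density on a 0.25 Hz grid (0 Hz to Nyquist),
#' obtained by averaging Hann-tapered periodograms of the selected 4 s
#' windows.  Uses R's mixed-radix FFT, so non-power-of-two window lengths
#' (e.g. 996 samples at 249 Hz) need no zero padding.  Normalization is
#' density-style (division by `sfreq * sum(w^2)` with one-sided doubling),
#' so the integral of the PSD over (0, Nyquist] matches signal variance for
#' broadband signals (Parseval).
#'
#' @param signal Numeric vector, microvolts.
#' @param sfreq Sampling rate in Hz.
#' @param starts Window start times in seconds (from [select_windows()]).
#' @param window_s Window length in seconds (default 4).
#' @param channel Channel label stored with the result.
#' @return Tibble (`nrem_spectra`) with columns `channel`, `frequency`,
#'   `power`, `n_windows`.
#' @export
average_periodogram <- function(signal, sfreq, starts, window_s = 4,
                                channel = "EEG") {
  if (length(starts) < 1) abort("at least one window is required")
  n <- as.integer(round(window_s * sfreq))
  w <- hann_window(n)
  norm <- sfreq * sum(w^2)
  n_half <- floor(n / 2)

  acc <- numeric(n_half + 1)
  for (t0 in starts) {
    i0 <- as.integer(round(t0 * sfreq))
    if (i0 < 0 || i0 + n > length(signal)) {
      abort(sprintf("window starting at %.2f s exceeds signal bounds", t0))
    }
    seg <- signal[(i0 + 1):(i0 + n)] * w
    sp <- abs(fft(seg)[1:(n_half + 1)])^2 / norm
    acc <- acc + sp
  }
  psd <- acc / length(starts)
  # one-sided doubling (DC and, for even n, Nyquist are unique bins)
  dbl <- rep(2, n_half + 1)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[n_half + 1] <- 1
  psd <- psd * dbl

  as_nrem_spectra(tibble::tibble(
    channel = channel,
    frequency = (0:n_half) / window_s,
    power = psd,
    n_windows = length(starts)
  ))
}

#' Compute calibrated NREM spectra for every channel of a recording
#'
#' Convenience pipeline: [select_windows()] then [average_periodogram()]
#' per channel, optionally followed by [apply_calibration()].
#'
#' @param recording An `nrem_recording`.
#' @param stages Accepted stage codes (default NREM: N2, N3).
#' @param calibration Optional `nrem_calibration` object.
#' @param window_s,overlap Passed to [select_windows()].
#' @return Tidy `nrem_spectra` tibble across channels.
#' @export
compute_spectra <- function(recording, stages = c("N2", "N3"),
                            calibration = NULL, window_s = 4, overlap = 0.5) {
  starts <- select_windows(recording, stages, window_s, overlap)
  out <- purrr::map_dfr(recording$channel_names, function(ch) {
    average_periodogram(recording$signals[[ch]], recording$sfreq,
                        starts, window_s, channel = ch)
  })
  if (!is.null(calibration)) out <- apply_calibration(out, calibration)
  as_nrem_spectra(out)
}

#' Build a device amplitude-calibration curve
#'
#' Amplitude reduction rates (measured/generated sinusoid amplitude) are
#' determined at anchor frequencies for two generator amplitudes (40 and
#' 355 uV), averaged per anchor, and interpolated between anchors by a
#' cubic spline.  Outside the anchor span the curve is clamped to the
#' boundary value.
#'
#' @param anchor_freqs Anchor frequencies in Hz (>= 4 anchors).
#' @param rates_40uV,rates_355uV Positive reduction rates per anchor.
#' @return An `nrem_calibration` object (callable interpolant plus anchors).
#' @export
build_calibration <- function(anchor_freqs, rates_40uV, rates_355uV) {
  stopifnot(length(anchor_freqs) == length(rates_40uV),
            length(anchor_freqs) == length(rates_355uV))
  if (length(anchor_freqs) < 4) {
    abort("at least 4 anchor frequencies are required for spline interpolation")
  }
  if (any(rates_40uV <= 0) || any(rates_355uV <= 0)) {
    abort("reduction rates must be positive")
  }
  ord <- order(anchor_freqs)
  f <- anchor_freqs[ord]
  rate <- (rates_40uV[ord] + rates_355uV[ord]) / 2
  if (any(rate > 1.5)) {
    abort("averaged reduction rate exceeds 1.5; check amplitude units")
  }
  sf <- splinefun(f, rate, method = "natural")
  structure(
    list(anchor_freqs = f, reduction_rate = rate,
         fmin = min(f), fmax = max(f), interpolant = sf),
    class = "nrem_calibration"
  )
}

#' Evaluate a calibration curve
#'
#' @param cal An `nrem_calibration`.
#' @param freq Frequencies in Hz (clamped to the anchor span).
#' @return Amplitude reduction rate at each frequency.
#' @export
calibration_rate <- function(cal, freq) {
  stopifnot(inherits(cal, "nrem_calibration"))
  cal$interpolant(pmin(pmax(freq, cal$fmin), cal$fmax))
}

#' Apply a device calibration to spectra
#'
#' Corrects measured PSD values by dividing by the squared amplitude
#' reduction rate at each frequency.
#'
#' @param spectra Tidy spectra tibble.
#' @param cal An `nrem_calibration`.
#' @return Spectra tibble with corrected `power`.
#' @export
apply_calibration <- function(spectra, cal) {
  rate <- calibration_rate(cal, spectra$frequency)
  if (any(rate <= 0)) {
    abort("calibration rate is non-positive on the spectrum grid")
  }
  spectra$power <- spectra$power / rate^2
  as_nrem_spectra(spectra)
}
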