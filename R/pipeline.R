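#' Full per-subject spectral parametrization
#'
#' One call from a spectra table to the composite parameter set: fits the
#' power-law background per channel ([fit_background()]), detects and
#' ranks whitened spindle-band peaks ([find_spindle_peaks()]), derives the
#' antero-posterior profile ([antero_posterior_profile()]) and labels each
#' channel slow- or fast-spindle dominant.
#'
#' @param spectra Tidy spectra tibble for one subject.
#' @param subject_id Subject identifier stored in the output.
#' @param fmin,fmax,exclude Background-fit settings (see [powerlaw_fit()]).
#' @param band Spindle search band in Hz.
#' @return Parameter tibble with one row per channel (the column set of
#'   [write_parameter_table()]); the `nrem_ap_profile` is attached as
#'   attribute `profile`.
#' @export
parametrize_spectra <- function(spectra, subject_id = "S001",
                                fmin = 2, fmax = 48,
                                exclude = c(6.0052, 17.9948),
                                band = c(9, 18)) {
  fits <- fit_background(spectra, fmin, fmax, exclude)
  peaks <- find_spindle_peaks(spectra, fits, band)
  out <- dplyr::left_join(fits, peaks, by = "channel")
  out$subject_id <- subject_id

  prof <- tryCatch(
    suppressWarnings(antero_posterior_profile(peaks)),
    error = function(e) NULL
  )
  if (!is.null(prof)) {
    cls <- stats::setNames(prof$channel_class$spindle_class,
                           prof$channel_class$channel)
    out$spindle_class <- unname(cls[out$channel])
  } else {
    out$spindle_class <- NA_character_
  }
  out <- dplyr::select(out, "subject_id", dplyr::everything())
  attr(out, "profile") <- prof
  out
}
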