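#' Plot spectra in the double-logarithmic plane
#'
#' @param spectra Tidy spectra tibble.
#' @param fmin Lowest frequency shown (default 0.5 Hz; 0 Hz cannot be
#'   log-scaled).
#' @return A ggplot object: ln P against ln f, one line per channel.
#' @export
plot_spectra <- function(spectra, fmin = 0.5) {
  df <- dplyr::filter(spectra, .data$frequency >= fmin, .data$power > 0)
  ggplot2::ggplot(df, ggplot2::aes(log(.data$frequency), log(.data$power),
                                   colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "ln frequency (ln Hz)",
                  y = expression("ln power (ln " * mu * V^2 * "/Hz)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn powerlaw_fit Plot the spectrum, the fitted background line
#'   and the excluded band.
#' @param object A `powerlaw_fit`.
#' @param spectrum Optional spectra tibble to draw under the fit.
#' @method autoplot powerlaw_fit
#' @export
autoplot.powerlaw_fit <- function(object, spectrum = NULL, ...) {
  rng <- log(object$fit_range)
  line_df <- tibble::tibble(
    lnf = seq(rng[1], rng[2], length.out = 200)
  )
  line_df$lnp <- evaluate_background(object, line_df$lnf)
  p <- ggplot2::ggplot(line_df, ggplot2::aes(.data$lnf, .data$lnp))
  if (!is.null(spectrum)) {
    sd <- dplyr::filter(spectrum,
                        .data$frequency >= object$fit_range[1],
                        .data$frequency <= object$fit_range[2],
                        .data$power > 0)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(lnf = log(sd$frequency), lnp = log(sd$power)),
      colour = "grey40")
  }
  p +
    ggplot2::annotate("rect",
                      xmin = log(object$excluded_band[1]),
                      xmax = log(object$excluded_band[2]),
                      ymin = -Inf, ymax = Inf, alpha = 0.12) +
    ggplot2::geom_line(colour = "red") +
    ggplot2::labs(x = "ln frequency (ln Hz)", y = "ln power",
                  title = sprintf("alpha = %.3f, lnC0 = %.3f, R2 = %.4f",
                                  object$alpha, object$lnC0, object$r2)) +
    ggplot2::theme_minimal()
}

#' Plot a whitened spectrum with its detected peaks
#'
#' @param spectrum One-channel spectra tibble.
#' @param fit A `powerlaw_fit` for that channel.
#' @param band Spindle search band (shaded).
#' @param peaks Optional `nrem_peaks` tibble to mark.
#' @return A ggplot of the whitened ln-power curve.
#' @export
plot_whitened <- function(spectrum, fit, band = c(9, 18), peaks = NULL) {
  sel <- spectrum$frequency >= fit$fit_range[1] &
    spectrum$frequency <= fit$fit_range[2] & spectrum$power > 0
  df <- tibble::tibble(
    frequency = spectrum$frequency[sel],
    whitened = log(spectrum$power[sel]) -
      evaluate_background(fit, log(spectrum$frequency[sel]))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$whitened)) +
    ggplot2::annotate("rect", xmin = band[1], xmax = band[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.12) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(frequency = peaks$freq,
                            whitened = peaks$whitened_amp),
      colour = "red")
  }
  p + ggplot2::labs(x = "frequency (Hz)",
                    y = expression("whitened ln " * P[Peak] * "(f)")) +
    ggplot2::theme_minimal()
}

#' @describeIn antero_posterior_profile Plot regional means and the
#'   maximal-shift boundary.
#' @param object An `nrem_ap_profile`.
#' @method autoplot nrem_ap_profile
#' @export
autoplot.nrem_ap_profile <- function(object, ...) {
  df <- object$region_means
  ggplot2::ggplot(df, ggplot2::aes(.data$region, .data$mean_f, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "sagittal region (anterior to posterior)",
                  y = expression(f[maxPeak] * " (Hz)"),
                  title = sprintf("total shift %.2f Hz; maximal at %s",
                                  object$total_shift,
                                  object$max_shift_location)) +
    ggplot2::theme_minimal()
}
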