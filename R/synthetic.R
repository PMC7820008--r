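#' Synthesize a power spectrum with known ground truth
#'
#' Realizes the spectral model directly on the 0.25 Hz grid:
#' `ln P(f) = lnC + alpha ln f + sum_j height_j exp(-(f - center_j)^2 /
#' (2 width_j^2)) + eps(f)` with `eps ~ N(0, noise_sd^2)` i.i.d.  Bumps are
#' Gaussian in linear frequency on the ln-power axis, so the maximizer of
#' the noiseless generating curve is available in closed form (numerically,
#' on a dense grid).
#'
#' @param lnC Background intercept at ln f = 0 (ln uV^2/Hz).
#' @param alpha Spectral exponent (typically -4 < alpha < -1).
#' @param bumps Tibble/data frame with columns `center` (Hz), `height`
#'   (ln-power units, >= 0), `width` (Hz, > 0); `NULL` for no bumps.
#' @param noise_sd SD of additive Gaussian noise on ln P (default 0).
#' @param fmin,fmax,step Frequency grid (defaults 0.25-62.5 Hz by 0.25).
#' @param channel Channel label.
#' @param seed Optional integer seed (local RNG; does not disturb the
#'   global stream).
#' @return `nrem_spectra` tibble; attribute `truth` holds the generating
#'   parameters.
#' @export
synth_spectrum <- function(lnC = 5, alpha = -2.5, bumps = NULL,
                           noise_sd = 0, fmin = 0.25, fmax = 62.5,
                           step = 0.25, channel = "C3", seed = NULL) {
  if (fmin <= 0 || fmax <= fmin) abort("need 0 < fmin < fmax")
  f <- seq(fmin, fmax, by = step)
  lnp <- lnC + alpha * log(f)
  if (!is.null(bumps) && nrow(bumps) > 0) {
    if (any(bumps$height < 0) || any(bumps$width <= 0)) {
      abort("bump heights must be >= 0 and widths > 0")
    }
    if (any(bumps$center < fmin | bumps$center > fmax)) {
      abort("bump centers must lie inside the frequency grid")
    }
    for (j in seq_len(nrow(bumps))) {
      lnp <- lnp + bumps$height[j] *
        exp(-(f - bumps$center[j])^2 / (2 * bumps$width[j]^2))
    }
  }
  if (noise_sd > 0) {
    lnp <- lnp + with_seed(seed, rnorm(length(f), 0, noise_sd))
  }
  out <- as_nrem_spectra(tibble::tibble(
    channel = channel, frequency = f, power = exp(lnp)
  ))
  attr(out, "truth") <- list(lnC = lnC, alpha = alpha, bumps = bumps,
                             noise_sd = noise_sd)
  out
}

#' Dense-grid peak oracle for a noiseless synthetic spectrum
#'
#' Independent oracle for peak localization: evaluates the full generating
#' curve `lnC + alpha ln f + bump field` of [synth_spectrum()] on a dense
#' frequency grid within `band`, enumerates its interior local maxima
#' (sample-wise), and ranks them by whitened value (curve minus
#' background).  Because of the tilted background, a bump's local maximum
#' sits slightly below the bump center; this brute-force enumeration gives
#' the reference location and whitened amplitude with no spline or
#' derivative machinery.
#'
#' @param lnC,alpha Background parameters of the generating curve.
#' @param bumps Bump table as in [synth_spectrum()].
#' @param band Search band in Hz.
#' @param resolution Dense grid step (default 1e-4 Hz).
#' @return List with `freq` and `whitened` of the top-ranked local
#'   maximum, plus `all` (tibble of every local maximum); `NULL` when the
#'   curve is monotone within the band.
#' @export
dense_peak_oracle <- function(lnC, alpha, bumps, band = c(9, 18),
                              resolution = 1e-4) {
  f <- seq(band[1], band[2], by = resolution)
  field <- numeric(length(f))
  for (j in seq_len(nrow(bumps))) {
    field <- field + bumps$height[j] *
      exp(-(f - bumps$center[j])^2 / (2 * bumps$width[j]^2))
  }
  curve <- lnC + alpha * log(f) + field
  n <- length(curve)
  i <- which(curve[2:(n - 1)] > curve[1:(n - 2)] &
               curve[2:(n - 1)] > curve[3:n]) + 1
  if (length(i) == 0) return(NULL)
  ord <- order(-field[i])
  all <- tibble::tibble(freq = f[i][ord], whitened = field[i][ord])
  list(freq = all$freq[1], whitened = all$whitened[1], all = all)
}

#' Synthesize a time-domain recording with 1/f background and spindles
#'
#' Colored noise is built by spectral shaping: Fourier amplitudes are set
#' to the target power law `C f^alpha` on the PSD scale, phases are drawn
#' uniformly, and the inverse transform gives the real signal.  Sleep
#' spindle events (Hann-enveloped sinusoids) are added at Poisson-placed
#' onsets.  The result is wrapped as an all-N2 `nrem_recording` with a
#' clean artifact mask, ready for [compute_spectra()].
#'
#' @param alpha Spectral exponent of the background.
#' @param lnC Background PSD intercept (ln uV^2/Hz at 1 Hz).
#' @param duration_s Recording length in seconds (>= 60).
#' @param sfreq Sampling rate in Hz.
#' @param spindle_rate Spindle events per minute (0 disables spindles).
#' @param spindle_freq Spindle oscillation frequency in Hz (9-18).
#' @param spindle_amp Spindle peak amplitude in uV.
#' @param spindle_dur Spindle duration in seconds.
#' @param channel Channel label.
#' @param seed Optional integer seed.
#' @return An `nrem_recording` with one channel; attribute `truth` stores
#'   the generating parameters.
#' @export
synth_timeseries <- function(alpha = -2.5, lnC = 5, duration_s = 1200,
                             sfreq = 250, spindle_rate = 6,
                             spindle_freq = 13.5, spindle_amp = 25,
                             spindle_dur = 1, channel = "C3", seed = NULL) {
  if (duration_s < 60) abort("duration must be at least 60 s")
  if (spindle_rate < 0) abort("spindle rate must be non-negative")
  if (spindle_rate > 0 && (spindle_freq < 9 || spindle_freq > 18)) {
    abort("spindle frequency must lie in 9-18 Hz")
  }
  x <- with_seed(seed, {
    n <- as.integer(round(duration_s * sfreq))
    freqs <- (1:(n %/% 2)) * sfreq / n
    psd <- exp(lnC) * freqs^alpha
    amp <- sqrt(psd * sfreq * n / 2)
    phase <- runif(length(freqs), 0, 2 * pi)
    pos <- complex(modulus = amp, argument = phase)
    spec <- complex(real = numeric(n))
    spec[2:(n %/% 2 + 1)] <- pos
    if (n %% 2 == 0) spec[n %/% 2 + 1] <- complex(real = amp[length(amp)])
    spec[n:(n %/% 2 + 2)] <- Conj(spec[2:(n %/% 2 + if (n %% 2 == 0) 0 else 1)])
    sig <- Re(fft(spec, inverse = TRUE)) / n
    if (spindle_rate > 0) {
      n_ev <- rpois(1, spindle_rate * duration_s / 60)
      dur_n <- as.integer(round(spindle_dur * sfreq))
      env <- hann_window(dur_n)
      for (k in seq_len(n_ev)) {
        t0 <- runif(1, 0, duration_s - spindle_dur)
        i0 <- as.integer(round(t0 * sfreq))
        tt <- (0:(dur_n - 1)) / sfreq
        sig[(i0 + 1):(i0 + dur_n)] <- sig[(i0 + 1):(i0 + dur_n)] +
          spindle_amp * env * sin(2 * pi * spindle_freq * (t0 + tt))
      }
    }
    sig
  })
  n_ep <- ceiling(duration_s / 20)
  rec <- new_recording(
    stats::setNames(list(x), channel), sfreq,
    epoch_stages = rep("N2", n_ep),
    artifact_mask = rep(FALSE, ceiling(duration_s / 4))
  )
  attr(rec, "truth") <- list(alpha = alpha, lnC = lnC,
                             spindle_rate = spindle_rate,
                             spindle_freq = spindle_freq,
                             spindle_amp = spindle_amp)
  rec
}

# antero-posterior base f_maxPeak per coronal row: regional means
# Fp 11.62, F 12.05, C 13.50, P 13.58, O 13.61 -> total shift 1.99 Hz with
# the maximal (1.45 Hz) step between the frontal and central rows
ROW_FMAX_BASE <- c(11.62, 12.05, 13.50, 13.58, 13.61)

#' Default planted effects for synthetic cohorts
#'
#' Effect sizes emulating the adult-cohort structure the package targets:
#' age-associated slope flattening (r = 0.45), age-related loss of spindle
#' peak amplitude (r = -0.3) and frequency (r = -0.25), higher slope-free
#' intercepts (+0.5 ln-units) and faster spindles (+0.35 Hz) in women, a
#' null sex effect on whitened peak amplitude, and an IQ-amplitude
#' correlation present in women (r = 0.3) but absent in men.
#'
#' @return Named list of planted effects, to pass to [synth_cohort()].
#' @export
cohort_effects <- function() {
  list(
    age_alpha = 0.45,
    age_lnPPeak = -0.3,
    age_fmax = -0.25,
    sex_lnC = 0.5,
    sex_fmax = 0.35,
    sex_lnPPeak = 0,
    iq_lnPPeak_female = 0.3,
    iq_lnPPeak_male = 0
  )
}

#' Planted-null effects (all zero)
#'
#' @return Effects list as [cohort_effects()] with every effect set to 0,
#'   for type-I error simulations.
#' @export
null_effects <- function() {
  e <- cohort_effects()
  lapply(e, function(x) 0)
}

#' Synthesize a cohort parameter table with planted effects
#'
#' Draws per-subject latent parameters from a Gaussian copula carrying the
#' planted correlations/mean shifts, then per-channel values as the subject
#' value plus independent channel noise (giving realistic high
#' inter-channel correlations).  The background intercept is constructed
#' so that the slope-free anchor sits at ln f = 2.5: `lnC_2.5` is drawn
#' independently of `alpha` and `lnC0 = lnC_2.5 - 2.5 alpha`.
#'
#' @param n_subjects Number of subjects (default 170).
#' @param effects Planted-effect list (see [cohort_effects()]).
#' @param age_range Age bounds in years (default 17-60).
#' @param p_female Proportion of women (default 81/175).
#' @param miss_rate Per-channel probability of a missing spindle peak.
#' @param channel_sd Named list of channel-noise SDs
#'   (`alpha`, `lnC`, `fmax`, `lnPPeak`).
#' @param seed Optional integer seed.
#' @return List with `params` (subject x channel parameter tibble),
#'   `covariates` (per-subject tibble) and `truth` (planted effects and
#'   generator settings).
#' @export
synth_cohort <- function(n_subjects = 170, effects = cohort_effects(),
                         age_range = c(17, 60), p_female = 81 / 175,
                         miss_rate = 0.03,
                         channel_sd = list(alpha = 0.08, lnC = 0.15,
                                           fmax = 0.2, lnPPeak = 0.12),
                         seed = NULL) {
  if (n_subjects < 1) abort("n_subjects must be positive")
  e <- utils::modifyList(cohort_effects(), effects %||% list())
  rho <- c(e$age_alpha, e$age_lnPPeak, e$age_fmax,
           e$iq_lnPPeak_female, e$iq_lnPPeak_male)
  if (any(abs(rho) >= 1)) abort("planted correlations must satisfy |rho| < 1")
  if (e$age_lnPPeak^2 + max(e$iq_lnPPeak_female^2, e$iq_lnPPeak_male^2) >= 1) {
    abort("infeasible effect combination on lnPPeak (variance exceeds 1)")
  }

  with_seed(seed, {
    n <- n_subjects
    z_age <- rnorm(n)
    z_iq <- rnorm(n)
    female <- runif(n) < p_female
    sex <- ifelse(female, "female", "male")
    age <- age_range[1] + diff(age_range) * pnorm(z_age)
    iq <- round(110 + 15 * z_iq)
    iq_group <- ifelse(iq >= 120, "HIQ", "AIQ")

    mix <- function(w, z) {
      resid <- sqrt(1 - sum(w^2))
      as.vector(z %*% w) + resid * rnorm(n)
    }
    z_alpha <- mix(e$age_alpha, cbind(z_age))
    w_iq <- ifelse(female, e$iq_lnPPeak_female, e$iq_lnPPeak_male)
    resid_amp <- sqrt(1 - e$age_lnPPeak^2 - w_iq^2)
    z_amp <- e$age_lnPPeak * z_age + w_iq * z_iq + resid_amp * rnorm(n)
    z_fmax <- mix(e$age_fmax, cbind(z_age))

    alpha_s <- -2.5 + 0.3 * z_alpha
    lnC25_s <- -1.5 + 0.5 * rnorm(n) + e$sex_lnC * female
    amp_s <- 0.8 + 0.25 * z_amp + e$sex_lnPPeak * female
    fdev_s <- 0.4 * z_fmax + e$sex_fmax * female

    subj_id <- sprintf("S%03d", seq_len(n))
    grid <- tidyr::expand_grid(subject_id = subj_id, channel = MONTAGE_18)
    i <- match(grid$subject_id, subj_id)
    m <- nrow(grid)
    row <- CHANNEL_ROW[grid$channel]

    alpha_c <- alpha_s[i] + rnorm(m, 0, channel_sd$alpha)
    lnC25_c <- lnC25_s[i] + rnorm(m, 0, channel_sd$lnC)
    fmax_c <- ROW_FMAX_BASE[row] + fdev_s[i] + rnorm(m, 0, channel_sd$fmax)
    amp_c <- amp_s[i] + rnorm(m, 0, channel_sd$lnPPeak)
    missing <- runif(m) < miss_rate
    fmax_c[missing] <- NA_real_
    amp_c[missing] <- NA_real_

    lnC0_c <- lnC25_c - 2.5 * alpha_c
    params <- tibble::tibble(
      subject_id = grid$subject_id,
      channel = grid$channel,
      alpha = alpha_c,
      lnC0 = lnC0_c,
      `lnC_2.0` = lnC0_c + 2.0 * alpha_c,
      `lnC_2.3` = lnC0_c + 2.3 * alpha_c,
      `lnC_2.5` = lnC25_c,
      `lnC_2.6` = lnC0_c + 2.6 * alpha_c,
      `lnC_2.7` = lnC0_c + 2.7 * alpha_c,
      `lnC_3.0` = lnC0_c + 3.0 * alpha_c,
      r2 = pmin(1, 0.995 + rnorm(m, 0, 0.002)),
      f_maxPeak = fmax_c,
      lnPPeak = amp_c,
      n_peaks = ifelse(missing, 0L, 1L),
      spindle_class = ifelse(row <= 2, "slow", "fast")
    )
    covariates <- tibble::tibble(
      subject_id = subj_id, age_years = age, sex = sex,
      iq_score = iq, iq_group = iq_group
    )
    list(params = params, covariates = covariates,
         truth = list(effects = e, n_subjects = n,
                      row_fmax_base = ROW_FMAX_BASE,
                      channel_sd = channel_sd))
  })
}

# evaluate `expr` under a locally seeded RNG without touching the caller's
# RNG state; seed = NULL uses (and advances) the global stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}
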