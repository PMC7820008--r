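#' Sagittal regional means of spindle peak frequency
#'
#' Averages per-channel `f_maxPeak` values within the five antero-posterior
#' regions: frontopolar (Fp1, Fp2), frontal (F3, F4, Fz), central (C3, C4,
#' Cz), parietal (P3, P4) and occipital (O1, O2).  Channels with missing
#' peaks are dropped from their region's mean; a region with no available
#' channel is `NA`.
#'
#' @param peaks Tibble with columns `channel` and `f_maxPeak` (one subject),
#'   e.g. from [find_spindle_peaks()].
#' @return Tibble with columns `region` (ordered Fp, F, C, P, O), `mean_f`
#'   and `n_channels`.
#' @export
regional_means <- function(peaks) {
  ch <- normalize_channel(peaks$channel)
  vals <- stats::setNames(peaks$f_maxPeak, ch)
  rows <- purrr::imap(REGION_CHANNELS, function(members, region) {
    v <- vals[names(vals) %in% members]
    v <- v[!is.na(v)]
    tibble::tibble(region = region,
                   mean_f = if (length(v)) mean(v) else NA_real_,
                   n_channels = length(v))
  })
  out <- dplyr::bind_rows(rows)
  if (all(is.na(out$mean_f))) abort("no region has any available f_maxPeak")
  out$region <- factor(out$region, levels = names(REGION_CHANNELS))
  out
}

#' Antero-posterior profile of spindle peak frequency
#'
#' Serially subtracts consecutive regional means (F-Fp, C-F, P-C, O-P),
#' sums the shifts, locates the maximal shift, and classifies every montage
#' channel as slow- (rostral to the maximal upward shift) or fast-spindle
#' dominant (caudal).  Temporal channels, which belong to no sagittal
#' region, are classified by their coronal row and flagged as extrapolated.
#'
#' @param means Output of [regional_means()] (or a subject's peaks tibble,
#'   which is passed through [regional_means()] first).
#' @return A list of class `nrem_ap_profile` with `region_means`, `shifts`
#'   (tibble: `boundary`, `shift_hz`), `total_shift`, `max_shift_location`,
#'   and `channel_class` (tibble: `channel`, `spindle_class`,
#'   `extrapolated`).
#' @export
antero_posterior_profile <- function(means) {
  if (!all(c("region", "mean_f") %in% names(means))) {
    means <- regional_means(means)
  }
  m <- stats::setNames(means$mean_f, as.character(means$region))
  m <- m[names(REGION_CHANNELS)]
  pairs <- cbind(anterior = c("Fp", "F", "C", "P"),
                 posterior = c("F", "C", "P", "O"))
  shift <- m[pairs[, "posterior"]] - m[pairs[, "anterior"]]
  boundary <- paste0(pairs[, "posterior"], "-", pairs[, "anterior"])
  ok <- !is.na(shift)
  if (sum(ok) < 1) abort("need at least 2 consecutive non-missing regions")
  total <- sum(shift[ok])
  mx <- max(shift[ok])
  at_max <- which(ok & shift == mx)
  if (length(at_max) > 1) {
    warn("tie for maximal antero-posterior shift; taking the most anterior")
  }
  loc <- boundary[at_max[1]]
  if (mx <= 0) warn("no upward antero-posterior frequency shift")

  # boundary sits between coronal rows at_max and at_max + 1
  boundary_row <- REGION_ROW[pairs[at_max[1], "anterior"]]
  cls <- tibble::tibble(
    channel = names(CHANNEL_ROW),
    spindle_class = ifelse(CHANNEL_ROW <= boundary_row, "slow", "fast"),
    extrapolated = !names(CHANNEL_ROW) %in% unlist(REGION_CHANNELS)
  )
  structure(
    list(
      region_means = means,
      shifts = tibble::tibble(boundary = boundary, shift_hz = unname(shift)),
      total_shift = total,
      max_shift_location = loc,
      channel_class = cls
    ),
    class = "nrem_ap_profile"
  )
}

#' @export
print.nrem_ap_profile <- function(x, ...) {
  cat(sprintf(
    "<nrem_ap_profile> total shift %.3f Hz, maximal shift at %s\n",
    x$total_shift, x$max_shift_location))
  invisible(x)
}

#' @rdname antero_posterior_profile
#' @param x An `nrem_ap_profile`.
#' @param ... Unused.
#' @method tidy nrem_ap_profile
#' @export
tidy.nrem_ap_profile <- function(x, ...) x$shifts

#' @rdname antero_posterior_profile
#' @method glance nrem_ap_profile
#' @export
glance.nrem_ap_profile <- function(x, ...) {
  tibble::tibble(total_shift = x$total_shift,
                 max_shift_location = x$max_shift_location,
                 n_slow = sum(x$channel_class$spindle_class == "slow"),
                 n_fast = sum(x$channel_class$spindle_class == "fast"))
}

#' Cohort antero-posterior topography summary
#'
#' Runs [antero_posterior_profile()] per subject and summarizes the cohort:
#' mean total shift, mean maximal shift, and the frequency table of the
#' maximal-shift boundary locations.
#'
#' @param peaks Tibble with `subject_id`, `channel`, `f_maxPeak`.
#' @return A list with `per_subject` (tibble: subject, total shift, maximal
#'   shift and its location) and `boundary_table` (proportion of subjects
#'   per boundary).
#' @export
cohort_topography <- function(peaks) {
  subj <- split(peaks, peaks$subject_id)
  per <- purrr::map_dfr(names(subj), function(id) {
    prof <- suppressWarnings(antero_posterior_profile(subj[[id]]))
    tibble::tibble(
      subject_id = id,
      total_shift = prof$total_shift,
      max_shift = max(prof$shifts$shift_hz, na.rm = TRUE),
      max_shift_location = prof$max_shift_location
    )
  })
  tab <- table(factor(per$max_shift_location,
                      levels = c("F-Fp", "C-F", "P-C", "O-P")))
  list(
    per_subject = per,
    boundary_table = tibble::tibble(
      boundary = names(tab),
      n = as.integer(tab),
      proportion = as.numeric(tab) / nrow(per)
    )
  )
}
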