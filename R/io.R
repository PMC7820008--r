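STAGE_ALIASES <- c(
  "w" = "W", "wake" = "W", "0" = "W",
  "n1" = "N1", "1" = "N1", "s1" = "N1",
  "n2" = "N2", "2" = "N2", "s2" = "N2",
  "n3" = "N3", "3" = "N3", "4" = "N3", "s3" = "N3", "s4" = "N3", "sws" = "N3",
  "r" = "R", "rem" = "R", "5" = "R"
)

normalize_stage <- function(x) {
  out <- STAGE_ALIASES[tolower(trimws(x))]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    abort(paste0(
      "unknown sleep stage code(s): ", paste(bad, collapse = ", "),
      "; accepted codes/aliases: ", paste(names(STAGE_ALIASES), collapse = ", ")
    ))
  }
  unname(out)
}

#' Read a hypnogram file
#'
#' Accepts either one stage code per line, or a two-column CSV with columns
#' `epoch_index` (0-based or 1-based, only order matters) and `stage`.
#' Stage codes are AASM (`W`, `N1`, `N2`, `N3`, `R`) with common aliases
#' (numbers 0-5, `S1`..`S4`, `wake`, `rem`) accepted case-insensitively.
#'
#' @param path Path to the hypnogram file.
#' @return Character vector of canonical stage codes, one per scoring epoch.
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path)) abort(paste0("hypnogram file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("hypnogram file is empty")
  if (grepl(",", lines[1])) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("epoch_index", "stage") %in% names(df))) {
      abort("CSV hypnogram must have columns epoch_index, stage")
    }
    df <- df[order(df$epoch_index), ]
    return(normalize_stage(df$stage))
  }
  normalize_stage(lines)
}

#' Read a 4 s artifact mask
#'
#' Accepts either one `0`/`1` per line (one value per 4 s segment, `1` =
#' artifactual), or a CSV of intervals with columns `start_s`, `end_s`;
#' intervals are snapped outward to the 4 s grid.
#'
#' @param path Path to the artifact file, or `NULL` for an all-clean mask.
#' @param n_segments Number of 4 s segments covering the recording
#'   (`ceiling(duration / 4)`).
#' @return Logical vector of length `n_segments`; `TRUE` marks artifact.
#' @export
read_artifacts <- function(path, n_segments) {
  mask <- rep(FALSE, n_segments)
  if (is.null(path)) return(mask)
  if (!file.exists(path)) abort(paste0("artifact file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(mask)
  if (grepl(",", lines[1])) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("start_s", "end_s") %in% names(df))) {
      abort("CSV artifact file must have columns start_s, end_s")
    }
    for (i in seq_len(nrow(df))) {
      lo <- floor(df$start_s[i] / 4) + 1
      hi <- ceiling(df$end_s[i] / 4)
      lo <- max(lo, 1); hi <- min(hi, n_segments)
      if (hi >= lo) mask[lo:hi] <- TRUE
    }
    return(mask)
  }
  vals <- suppressWarnings(as.integer(trimws(lines)))
  if (anyNA(vals) || any(!vals %in% c(0L, 1L))) {
    abort("per-segment artifact file must contain only 0/1 values")
  }
  m <- min(length(vals), n_segments)
  mask[seq_len(m)] <- vals[seq_len(m)] == 1L
  mask
}

#' Assemble a recording bundle from EDF + hypnogram + artifact files
#'
#' Binds the three polysomnography inputs of the pipeline into one
#' consistent object: per-channel signals in microvolts, a per-epoch stage
#' sequence (default 20 s epochs) and a per-4 s artifact mask.  The signal
#' is truncated to the scored duration when the hypnogram is shorter than
#' the recording (with a warning); a hypnogram longer than the recording by
#' more than one epoch is an error.
#'
#' @param edf_path Path to the EDF file.
#' @param hypnogram_path Path to the hypnogram file (see [read_hypnogram()]).
#' @param artifact_path Optional path to the artifact file
#'   (see [read_artifacts()]); `NULL` means no artifacts.
#' @param channels Optional channel subset (case-insensitive).
#' @param epoch_length_s Scoring epoch length in seconds (default 20).
#' @return An object of class `nrem_recording`: a list with `signals`,
#'   `sfreq`, `channel_names`, `epoch_stages`, `epoch_length_s`,
#'   `artifact_mask`.
#' @export
read_recording <- function(edf_path, hypnogram_path, artifact_path = NULL,
                           channels = NULL, epoch_length_s = 20) {
  edf <- read_edf(edf_path, channels = channels)
  stages <- read_hypnogram(hypnogram_path)
  new_recording(edf$signals, edf$sfreq, stages,
                epoch_length_s = epoch_length_s,
                artifact_path = artifact_path)
}

# shared constructor/validator used by read_recording and the simulator
new_recording <- function(signals, sfreq, epoch_stages, epoch_length_s = 20,
                          artifact_mask = NULL, artifact_path = NULL) {
  n <- unique(lengths(signals))
  if (length(n) != 1) {
    bad <- names(signals)[lengths(signals) != lengths(signals)[1]]
    abort(paste0("channels differ in length: ", paste(bad, collapse = ", ")))
  }
  duration <- n / sfreq
  scored <- length(epoch_stages) * epoch_length_s
  if (scored > duration + epoch_length_s) {
    abort(sprintf(
      "hypnogram covers %.0f s but the recording lasts only %.1f s",
      scored, duration))
  }
  if (scored < duration) {
    warn(sprintf(
      "recording (%.1f s) longer than scored duration (%.0f s); truncating",
      duration, scored))
    keep <- seq_len(scored * sfreq)
    signals <- lapply(signals, function(x) x[keep])
    duration <- scored
  }
  n_seg <- ceiling(duration / 4)
  if (is.null(artifact_mask)) {
    artifact_mask <- read_artifacts(artifact_path, n_seg)
  }
  stopifnot(length(artifact_mask) == n_seg)
  structure(
    list(
      signals = signals,
      sfreq = sfreq,
      channel_names = names(signals),
      epoch_stages = epoch_stages,
      epoch_length_s = epoch_length_s,
      artifact_mask = artifact_mask
    ),
    class = "nrem_recording"
  )
}

#' @export
print.nrem_recording <- function(x, ...) {
  cat(sprintf(
    "<nrem_recording> %d channel(s) @ %g Hz, %.0f s, %d x %g s epochs, %d artifact segment(s)\n",
    length(x$signals), x$sfreq,
    length(x$signals[[1]]) / x$sfreq,
    length(x$epoch_stages), x$epoch_length_s,
    sum(x$artifact_mask)))
  invisible(x)
}

#' Read a table of precomputed power spectra
#'
#' Expects a CSV whose first column `frequency_hz` is a strictly increasing
#' uniform 0.25 Hz grid, with one additional column per channel holding
#' non-negative power spectral density values (uV^2/Hz).
#'
#' @param path CSV path.
#' @return A tidy tibble with columns `channel`, `frequency`, `power`
#'   (class `nrem_spectra`).
#' @export
read_spectra_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "frequency_hz") {
    abort("first column must be named frequency_hz")
  }
  f <- df$frequency_hz
  steps <- unique(round(diff(f), 10))
  if (length(steps) != 1 || steps[1] != 0.25) {
    abort(paste0("frequency grid must be uniform with 0.25 Hz step; observed step(s): ",
                 paste(utils::head(steps, 5), collapse = ", ")))
  }
  long <- tidyr::pivot_longer(df, -"frequency_hz",
                              names_to = "channel", values_to = "power")
  if (any(long$power < 0, na.rm = TRUE)) {
    bad <- which(long$power < 0)[1]
    abort(paste0("negative power value at row ", bad))
  }
  out <- dplyr::arrange(
    dplyr::transmute(long,
                     channel = normalize_channel(.data$channel),
                     frequency = .data$frequency_hz,
                     power = .data$power),
    .data$channel, .data$frequency)
  as_nrem_spectra(out)
}

#' Write a table of power spectra
#'
#' Inverse of [read_spectra_table()]: wide CSV with a `frequency_hz` column
#' and one column per channel.
#'
#' @param spectra Tidy spectra tibble (`channel`, `frequency`, `power`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(spectra, path) {
  wide <- tidyr::pivot_wider(
    dplyr::select(spectra, "channel", "frequency", "power"),
    names_from = "channel", values_from = "power")
  names(wide)[1] <- "frequency_hz"
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

PARAMETER_COLUMNS <- c(
  "subject_id", "channel", "alpha", "lnC0",
  "lnC_2.0", "lnC_2.3", "lnC_2.5", "lnC_2.6", "lnC_2.7", "lnC_3.0",
  "r2", "f_maxPeak", "lnPPeak", "n_peaks", "spindle_class"
)

#' Write the per-subject, per-channel parameter table
#'
#' Stable-column-order CSV of the composite spectral parameters.  Subjects
#' with no detected spectral peak in the spindle range carry empty
#' `f_maxPeak` / `lnPPeak` cells (missing data).
#'
#' @param params Tibble with (a subset of) the documented columns; missing
#'   columns are filled with `NA`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(params, path) {
  for (col in PARAMETER_COLUMNS) {
    if (!col %in% names(params)) params[[col]] <- NA
  }
  readr::write_csv(params[PARAMETER_COLUMNS], path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a parameter table written by [write_parameter_table()]
#'
#' @param path CSV path.
#' @return Tibble with the documented parameter columns.
#' @export
read_parameter_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    subject_id = readr::col_character(),
                    channel = readr::col_character(),
                    spindle_class = readr::col_character(),
                    .default = readr::col_double()))
}

#' Read a subject covariates table
#'
#' @param path CSV with columns `subject_id`, `age_years`, `sex`,
#'   `iq_score`, `iq_group` (extra columns pass through).
#' @return Tibble of covariates.
#' @export
read_covariates <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "age_years", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0("covariates file missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  df$subject_id <- as.character(df$subject_id)
  df
}

as_nrem_spectra <- function(x) {
  class(x) <- unique(c("nrem_spectra", class(x)))
  x
}
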