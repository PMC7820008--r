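#' Read a continuous EDF recording
#'
#' Minimal reader for the European Data Format (EDF, 16-bit integer samples,
#' continuous recording).  All requested signals must share one sampling
#' rate.  Digital values are mapped to physical units (microvolts for EEG)
#' by the per-signal linear calibration stored in the header.
#'
#' @param path Path to an `.edf` file.
#' @param channels Optional character vector of channel labels to keep
#'   (case-insensitive); default keeps every signal in the file.
#' @return A list with elements `signals` (named list of numeric vectors),
#'   `sfreq` (Hz) and `channel_names`.
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) abort(paste0("EDF file not found: ", path))
  con <- file(path, "rb")
  on.exit(close(con))

  hdr_ascii <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr_ascii(8)                        # version
  hdr_ascii(80); hdr_ascii(80)        # patient / recording id
  hdr_ascii(8); hdr_ascii(8)          # start date / time
  header_bytes <- as.integer(hdr_ascii(8))
  hdr_ascii(44)                       # reserved
  n_records <- as.integer(hdr_ascii(8))
  record_dur <- as.numeric(hdr_ascii(8))
  ns <- as.integer(hdr_ascii(4))

  field <- function(width) vapply(seq_len(ns), function(i) hdr_ascii(width), "")
  labels <- field(16)
  field(80)                           # transducer
  field(8)                            # physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)                           # prefiltering
  spr <- as.integer(field(8))         # samples per record per signal
  field(32)                           # reserved
  seek(con, header_bytes)

  # strip the conventional "EEG " signal-type prefix from labels
  labels <- sub("^EEG[ _]+", "", labels)

  keep <- seq_len(ns)
  if (!is.null(channels)) {
    keep <- match(tolower(channels), tolower(labels))
    if (anyNA(keep)) {
      abort(paste0("channels not present in EDF: ",
                   paste(channels[is.na(keep)], collapse = ", ")))
    }
  }

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min

  chunks <- vector("list", ns)
  for (i in seq_len(ns)) chunks[[i]] <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      x <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                   endian = "little")
      chunks[[i]][[r]] <- x
    }
  }

  rates <- spr[keep] / record_dur
  if (length(unique(rates)) != 1) {
    abort(paste0("selected EDF signals have differing sampling rates: ",
                 paste(unique(rates), collapse = ", ")))
  }

  signals <- lapply(keep, function(i) {
    unlist(chunks[[i]], use.names = FALSE) * gain[i] + offset[i]
  })
  names(signals) <- normalize_channel(labels[keep])
  list(signals = signals, sfreq = rates[1], channel_names = names(signals))
}

#' Write a continuous EDF recording
#'
#' Counterpart of [read_edf()]: writes one continuous 16-bit EDF file with
#' 1 s data records.  Physical range is taken from the data (symmetric,
#' padded by 1%%) so the quantization step is `range/65535`.
#'
#' @param signals Named list of numeric vectors (microvolts), equal lengths.
#' @param sfreq Sampling rate in Hz (integer-valued).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, sfreq, path) {
  stopifnot(is.list(signals), length(signals) >= 1, sfreq == round(sfreq))
  n <- unique(lengths(signals))
  if (length(n) != 1) abort("all signals must have equal length")
  n_records <- floor(n / sfreq)
  if (n_records < 1) abort("signal shorter than one 1 s data record")
  ns <- length(signals)

  fmt8 <- function(x) {
    for (d in 7:1) {
      s <- formatC(x, format = "g", digits = d)
      if (nchar(s) <= 8) return(s)
    }
    s
  }
  lim <- vapply(signals, function(x) max(abs(range(x)), 1e-6), 0) * 1.01
  # use the header-representable value so read_edf reproduces the gain exactly
  lim <- as.numeric(vapply(lim, fmt8, ""))
  gain <- (2 * lim) / (2^16 - 1)

  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    s <- formatC(as.character(x), width = w, flag = "-")
    writeChar(substr(s, 1, w), con, nchars = w, eos = NULL)
  }
  num <- function(x, w) pad(fmt8(x), w)

  pad("0", 8); pad("X X X X", 80); pad("Startdate X X X X", 80)
  pad("01.01.00", 8); pad("00.00.00", 8)
  pad(256 + ns * 256, 8); pad("", 44)
  pad(n_records, 8); pad(1, 8); pad(ns, 4)
  for (ch in names(signals)) pad(paste("EEG", ch), 16)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (i in seq_len(ns)) num(-lim[i], 8)
  for (i in seq_len(ns)) num(lim[i], 8)
  for (i in seq_len(ns)) pad(-32768, 8)
  for (i in seq_len(ns)) pad(32767, 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(sfreq, 8)
  for (i in seq_len(ns)) pad("", 32)

  dig <- lapply(seq_len(ns), function(i) {
    d <- round(signals[[i]] / gain[i])
    pmin(pmax(d, -32768), 32767)
  })
  for (r in seq_len(n_records)) {
    idx <- ((r - 1) * sfreq + 1):(r * sfreq)
    for (i in seq_len(ns)) {
      writeBin(as.integer(dig[[i]][idx]), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
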