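#' Write a recording to an EDF file
#'
#' Minimal single-record-rate European Data Format writer: 16-bit samples,
#' one-second data records, per-channel physical scaling chosen from the data
#' range. Requires an integer sampling rate and pads the signal to a whole
#' number of seconds with zeros.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  x <- rec$data
  nch <- nrow(x)
  n_rec <- ceiling(ncol(x) / fs)
  if (ncol(x) < n_rec * fs) {
    x <- cbind(x, matrix(0, nch, n_rec * fs - ncol(x)))
  }
  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  pad <- function(s, width) {
    s <- substr(as.character(s), 1, width)
    formatC(s, width = width, flag = "-")
  }
  num <- function(v, width) {
    vapply(v, function(z) {
      for (digits in 7:1) {           # widest representation that fits
        s <- sprintf("%.*g", digits, z)
        if (nchar(s) <= width) return(pad(s, width))
      }
      stop("cannot format ", z, " in ", width, " chars")
    }, "")
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8),
    pad(rec$subject_id, 80),
    pad(paste0("label=", ifelse(is.na(rec$label), "NA", rec$label)), 80),
    pad("01.01.20", 8), pad("00.00.00", 8),
    pad(256 * (1 + nch), 8), pad("", 44),
    pad(n_rec, 8), pad("1", 8), pad(nch, 4)
  ), con, eos = NULL)
  writeChar(paste0(
    paste(pad(rec$channel_names, 16), collapse = ""),
    paste(rep(pad("", 80), nch), collapse = ""),
    paste(rep(pad("uV", 8), nch), collapse = ""),
    paste(num(pmin_, 8), collapse = ""),
    paste(num(pmax_, 8), collapse = ""),
    paste(rep(pad(dmin, 8), nch), collapse = ""),
    paste(rep(pad(dmax, 8), nch), collapse = ""),
    paste(rep(pad("", 80), nch), collapse = ""),
    paste(rep(pad(fs, 8), nch), collapse = ""),
    paste(rep(pad("", 32), nch), collapse = "")
  ), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(nch)) {
      dig <- round((x[ch, cols] - pmin_[ch]) * scale[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads a continuous EDF recording with a common sampling rate across
#' signals, rescales to physical units and normalizes channel names against
#' the montage alias table (e.g. T7 -> T3).
#'
#' @param path EDF file path.
#' @param subject_id Optional subject ID override; defaults to the EDF
#'   patient-identification field.
#' @param label Optional class label override; defaults to a `label=` tag in
#'   the recording-identification field, if present.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, subject_id = NULL, label = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) trimws(readChar(con, nchars, useBytes = TRUE))
  readChar(con, 8)                       # version
  patient <- rd(80)
  recording <- rd(80)
  rd(8); rd(8)                           # date, time
  rd(8); rd(44)                          # header bytes, reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(nch), function(i) readChar(con, 16), ""))
  for (i in seq_len(nch)) readChar(con, 80)   # transducer
  for (i in seq_len(nch)) readChar(con, 8)    # phys dim
  pmin_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) readChar(con, 80)   # prefiltering
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) readChar(con, 32)   # reserved
  if (length(unique(spr)) != 1) {
    stop("mixed per-signal sampling rates are not supported")
  }
  fs <- spr[1] / rec_dur
  data <- matrix(0, nch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nch)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little")
      cols <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      data[ch, cols] <- pmin_[ch] +
        (dig - dmin[ch]) * (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
    }
  }
  if (is.null(label) && grepl("label=", recording)) {
    label <- sub(".*label=([^ ]+).*", "\\1", recording)
    if (identical(label, "NA")) label <- NA_character_
  }
  eeg_recording(data, fs, normalize_channel_names(labels),
                subject_id = subject_id %||% patient,
                label = label %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort as EDF files plus a manifest
#'
#' One EDF per subject plus a plain-text CSV manifest with columns
#' `subject_id`, `label`, `path`, so synthetic and real data enter the
#' pipeline identically.
#'
#' @param recordings List of [eeg_recording()] objects.
#' @param dir Output directory (created if absent).
#' @return Path of the manifest file, invisibly.
#' @export
write_cohort_edf <- function(recordings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(recordings, function(rec) {
    p <- file.path(dir, paste0(rec$subject_id, ".edf"))
    write_edf(rec, p)
    data.frame(subject_id = rec$subject_id, label = rec$label, path = p,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a cohort manifest and its EDF files
#'
#' @param manifest_path Path to a manifest written by [write_cohort_edf()].
#' @return List of [eeg_recording()] objects.
#' @export
read_cohort_edf <- function(manifest_path) {
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(base, basename(p))
    read_edf(p, subject_id = manifest$subject_id[i], label = manifest$label[i])
  })
}
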