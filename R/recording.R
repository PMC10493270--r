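#' EEG recording container
#'
#' One subject's multichannel time series: a channels-by-samples numeric
#' matrix (microvolts) with its sampling rate, ordered channel names, subject
#' identifier and optional class label.
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_names Character vector, one name per row of `data`.
#' @param subject_id Subject identifier.
#' @param label Class label (one of [class_labels()]) or `NA` for unlabeled
#'   data.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = rownames(data),
                          subject_id = "S1", label = NA_character_) {
  data <- as.matrix(data)
  if (is.null(channel_names)) stop("channel_names required")
  if (nrow(data) != length(channel_names)) {
    stop("channel count (", nrow(data), ") != number of channel names (",
         length(channel_names), ")")
  }
  if (fs <= 0) stop("fs must be positive")
  if (anyNA(data)) stop("recording contains NA values")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 subject_id = subject_id, label = label),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s]: %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, ifelse(is.na(x$label), "unlabeled", x$label),
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

duration_s <- function(rec) ncol(rec$data) / rec$fs

# Replace the data matrix, keeping metadata.
set_data <- function(rec, data) {
  rec$data <- data
  rec
}

#' Resample a recording to a target rate
#'
#' Linear-phase resampling via FFT (periodic extension); used to bring
#' heterogeneous acquisition rates onto a common rate before filtering.
#'
#' @param rec An [eeg_recording()].
#' @param fs_target Target sampling rate in Hz.
#' @return An [eeg_recording()] at `fs_target`.
#' @export
resample_recording <- function(rec, fs_target) {
  if (fs_target == rec$fs) return(rec)
  n_in <- ncol(rec$data)
  n_out <- round(n_in * fs_target / rec$fs)
  out <- t(apply(rec$data, 1, fft_resample, n_out = n_out))
  rownames(out) <- rec$channel_names
  rec$data <- out
  rec$fs <- fs_target
  rec
}

fft_resample <- function(x, n_out) {
  n_in <- length(x)
  X <- fft(x)
  Y <- complex(n_out)
  keep <- min(n_in, n_out)
  half <- floor((keep - 1) / 2)
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (half > 0) Y[(n_out - half + 1):n_out] <- X[(n_in - half + 1):n_in]
  Re(fft(Y, inverse = TRUE)) / n_in
}
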