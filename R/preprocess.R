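#' Common average reference over the 16 scalp electrodes
#'
#' Drops the ear electrodes A1/A2 and subtracts, at every sample, the mean of
#' the remaining 16 scalp channels. After re-referencing the cross-channel
#' mean is identically zero.
#'
#' @param rec An [eeg_recording()] containing at least the 16 scalp channels.
#' @return An [eeg_recording()] with exactly 16 channels.
#' @export
average_reference <- function(rec) {
  scalp <- montage_scalp16()
  missing <- setdiff(scalp, rec$channel_names)
  if (length(missing)) {
    stop("montage error: missing scalp channel(s): ",
         paste(missing, collapse = ", "))
  }
  x <- rec$data[scalp, , drop = FALSE]
  x <- sweep(x, 2, colMeans(x))
  rec$data <- x
  rec$channel_names <- scalp
  rec
}

#' Z-score normalization per channel
#'
#' Standardizes each channel over the whole recording to mean 0 and unit
#' standard deviation, X* = (X - mu) / delta, using the population (1/n)
#' standard deviation. Scope is per channel so that inter-channel amplitude
#' topography within a recording is preserved.
#'
#' @param rec An [eeg_recording()].
#' @return Standardized [eeg_recording()].
#' @export
zscore <- function(rec) {
  mu <- rowMeans(rec$data)
  xc <- rec$data - mu
  delta <- sqrt(rowMeans(xc^2))
  if (any(delta < 1e-12)) {
    stop("flat channel(s) with zero standard deviation: ",
         paste(rec$channel_names[delta < 1e-12], collapse = ", "))
  }
  set_data(rec, xc / delta)
}

#' Cut a recording into 60-s segments of twenty 3-s pieces
#'
#' Non-overlapping, left-aligned segmentation; a trailing remainder shorter
#' than `segment_s` is dropped. Each segment records the sample index ranges
#' of its `segment_s / piece_s` pieces, which tile it without gap or overlap.
#'
#' @param rec An [eeg_recording()].
#' @param segment_s Segment length in seconds.
#' @param piece_s Piece length in seconds; must divide `segment_s`.
#' @return List of `eeg_segment` objects (possibly empty, with a warning,
#'   when the recording is shorter than one segment).
#' @export
segment_recording <- function(rec, segment_s = 60, piece_s = 3) {
  if (segment_s %% piece_s != 0) stop("piece_s must divide segment_s")
  spseg <- round(segment_s * rec$fs)
  n_seg <- floor(ncol(rec$data) / spseg)
  if (n_seg == 0) {
    warning("recording shorter than one ", segment_s, "-s segment; ",
            "returning no segments")
    return(list())
  }
  n_pieces <- segment_s / piece_s
  sppiece <- round(piece_s * rec$fs)
  lapply(seq_len(n_seg), function(i) {
    cols <- ((i - 1) * spseg + 1):(i * spseg)
    structure(
      list(data = rec$data[, cols, drop = FALSE], fs = rec$fs,
           channel_names = rec$channel_names,
           piece_starts = (seq_len(n_pieces) - 1) * sppiece + 1,
           piece_len = sppiece,
           subject_id = rec$subject_id, label = rec$label, segment_index = i),
      class = "eeg_segment"
    )
  })
}

#' Short-time Fourier transform power of one signal piece
#'
#' Hann-windowed one-sided STFT returning a nonnegative power-density matrix
#' (frequency bins x frames), scaled as |STFT|^2 / (fs * sum(w^2)) with
#' interior bins doubled, so integrating over frequency recovers signal
#' power (Parseval up to the window correction).
#'
#' @param x Numeric vector (one channel of one piece).
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds; must not exceed the piece.
#' @param overlap Fractional window overlap in \[0, 1).
#' @return Matrix with attributes `freq` (Hz) and `time` (frame centers, s).
#' @export
stft_power <- function(x, fs, window_s = 1, overlap = 0.5) {
  nw <- round(window_s * fs)
  if (nw > length(x)) stop("window (", nw, " samples) longer than signal (",
                           length(x), " samples)")
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  hop <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1, length(x) - nw + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nw) - 1) / nw)   # periodic Hann
  frames <- vapply(starts, function(s) x[s:(s + nw - 1)] * w,
                   numeric(nw))
  spec <- mvfft(frames)
  nf <- floor(nw / 2) + 1
  p <- Mod(spec[seq_len(nf), , drop = FALSE])^2 / (fs * sum(w^2))
  if (nf > 2) {
    interior <- 2:(nf - 1 + nw %% 2)       # all but DC (and Nyquist if even)
    p[interior, ] <- 2 * p[interior, ]
  }
  structure(p,
            freq = (seq_len(nf) - 1) * fs / nw,
            time = (starts - 1 + nw / 2) / fs)
}

#' Concatenated power-density (CPD) maps of one segment
#'
#' Computes the STFT power map of each 3-s piece of the segment and
#' concatenates the per-piece maps along the time axis, one map per channel.
#' The frequency axis is truncated to `[0, fmax]` Hz (the filtering band).
#'
#' @param segment An `eeg_segment` from [segment_recording()].
#' @param window_s,overlap STFT parameters, see [stft_power()].
#' @param fmax Upper frequency bound in Hz.
#' @return List of `cpd_map` objects (fields `values` - nonnegative power,
#'   `freq`, `channel_name`, `subject_id`, `label`, `segment_index`), one per
#'   channel.
#' @export
build_cpd <- function(segment, window_s = 1, overlap = 0.5, fmax = 70) {
  stopifnot(inherits(segment, "eeg_segment"))
  n_pieces <- length(segment$piece_starts)
  lapply(seq_along(segment$channel_names), function(ch) {
    blocks <- lapply(seq_len(n_pieces), function(k) {
      s0 <- segment$piece_starts[k]
      piece <- segment$data[ch, s0:(s0 + segment$piece_len - 1)]
      stft_power(piece, segment$fs, window_s, overlap)
    })
    freq <- attr(blocks[[1]], "freq")
    keep <- freq <= fmax
    values <- do.call(cbind, lapply(blocks, function(b) b[keep, , drop = FALSE]))
    structure(
      list(values = unname(values), freq = freq[keep],
           channel_name = segment$channel_names[ch],
           subject_id = segment$subject_id, label = segment$label,
           segment_index = segment$segment_index),
      class = "cpd_map"
    )
  })
}

#' Full preprocessing pipeline: recording to CPD maps
#'
#' Applies, in fixed order: resampling to `cfg$fs` (if needed), band-pass
#' filter, notch filter, optional ICA component exclusion, common average
#' reference (dropping A1/A2), per-channel z-scoring, segmentation into 60-s
#' segments of twenty 3-s pieces, STFT and time-concatenation into one CPD
#' map per channel per segment.
#'
#' @param rec An [eeg_recording()] on the 18-channel acquisition montage.
#' @param cfg List of parameters, see [preprocess_config()].
#' @return List of segments' CPD-map lists, flattened: a list with one
#'   element per segment, each a list of 16 `cpd_map` objects.
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config()) {
  rec <- resample_recording(rec, cfg$fs)
  rec <- bandpass_filter(rec, cfg$bandpass_low, cfg$bandpass_high)
  rec <- notch_filter(rec, cfg$notch_freq)
  if (length(cfg$ica_exclude)) {
    rec <- apply_component_exclusion(rec, cfg$ica_exclude)
  }
  rec <- average_reference(rec)
  rec <- zscore(rec)
  segments <- segment_recording(rec, cfg$segment_s, cfg$piece_s)
  lapply(segments, build_cpd, window_s = cfg$stft_window_s,
         overlap = cfg$stft_overlap, fmax = cfg$fmax)
}

#' Preprocessing configuration
#'
#' @param fs Common sampling rate recordings are resampled to, Hz.
#' @param bandpass_low,bandpass_high Band-pass edges, Hz.
#' @param notch_freq Mains notch frequency, Hz.
#' @param ica_exclude Integer indices of ICA components to remove (empty by
#'   default: component review is a manual, expert step).
#' @param segment_s,piece_s Segmentation lengths, seconds.
#' @param stft_window_s,stft_overlap STFT window and fractional overlap.
#' @param fmax CPD frequency-axis upper bound, Hz.
#' @return Named list of preprocessing parameters.
#' @export
preprocess_config <- function(fs = 200, bandpass_low = 0.1,
                              bandpass_high = 70, notch_freq = 50,
                              ica_exclude = integer(0),
                              segment_s = 60, piece_s = 3,
                              stft_window_s = 1, stft_overlap = 0.5,
                              fmax = 70) {
  list(fs = fs, bandpass_low = bandpass_low, bandpass_high = bandpass_high,
       notch_freq = notch_freq, ica_exclude = ica_exclude,
       segment_s = segment_s, piece_s = piece_s,
       stft_window_s = stft_window_s, stft_overlap = stft_overlap,
       fmax = fmax)
}
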