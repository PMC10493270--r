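# IIR filter design and zero-phase application.
#
# Digital Butterworth low/high-pass via the bilinear transform of the analog
# prototype, and a constrained biquad notch. Filters are applied
# forward-backward (zero phase), so the quoted orders double in effect.

butter_coeffs <- function(n, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (fc <= 0 || fc >= fs / 2) stop("cutoff must lie in (0, fs/2)")
  Wc <- tan(pi * fc / fs)                       # prewarped, T = 2 convention
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))   # unit LP prototype poles
  if (type == "low") {
    pa <- Wc * proto
    za <- rep(-1 + 0i, n)                       # digital zeros at z = -1
  } else {
    pa <- Wc / proto
    za <- rep(1 + 0i, n)                        # digital zeros at z = +1
  }
  pz <- (1 + pa) / (1 - pa)                     # bilinear transform
  b <- Re(poly_from_roots(za))
  a <- Re(poly_from_roots(pz))
  ref <- if (type == "low") 1 + 0i else -1 + 0i # unity gain at DC / Nyquist
  gain <- Mod(polyval_z(a, ref) / polyval_z(b, ref))
  list(b = b * gain, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

polyval_z <- function(coef, z) {
  # coef in descending powers of z^{-1}: coef[1] + coef[2] z^-1 + ...
  sum(coef * z^(-(seq_along(coef) - 1)))
}

# Steady-state initial filter state (unit step input settles immediately).
lfilter_zi <- function(b, a) {
  m <- max(length(a), length(b)) - 1
  if (m == 0) return(numeric(0))
  bb <- c(b, rep(0, m + 1 - length(b))) / a[1]
  aa <- c(a, rep(0, m + 1 - length(a))) / a[1]
  # companion matrix of the denominator, transposed form
  A <- rbind(-aa[-1], cbind(diag(1, m - 1, m - 1), 0))
  B <- bb[-1] - aa[-1] * bb[1]
  solve(diag(m) - t(A), B)
}

# IIR filtering with initial conditions scaled to the first sample.
iir_filter <- function(b, a, x, zi = NULL) {
  if (is.null(zi)) zi <- numeric(max(length(a), length(b)) - 1)
  as.numeric(.iir_filter_cpp(b / a[1], a / a[1], x, zi))
}

# Zero-phase filtering: even-reflection edge padding (no DC step for
# zero-mean oscillatory signals, so slow high-pass poles stay quiet) plus
# steady-state initialization; the pad also covers high-Q ring-down.
filtfilt_1d <- function(b, a, x, pad = 300) {
  np <- max(3 * (max(length(a), length(b)) - 1), pad)
  np <- min(np, length(x) - 1)
  head_pad <- x[seq(np + 1, 2, by = -1)]
  tail_pad <- x[seq(length(x) - 1, length(x) - np)]
  xp <- c(head_pad, x, tail_pad)
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, xp, zi * xp[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(np + 1):(np + length(x))]
}

apply_filter_rec <- function(rec, b, a) {
  out <- t(apply(rec$data, 1, function(x) filtfilt_1d(b, a, x)))
  rownames(out) <- rec$channel_names
  set_data(rec, out)
}

#' Band-pass filter a recording
#'
#' Zero-phase Butterworth band-pass implemented as a cascade of an order-2
#' high-pass at `low` and an order-4 low-pass at `high` (orders double in
#' effect because filtering is forward-backward). Defaults match the clinical
#' preprocessing band of 0.1-70 Hz.
#'
#' @param rec An [eeg_recording()].
#' @param low High-pass edge in Hz.
#' @param high Low-pass edge in Hz; must be below the Nyquist frequency.
#' @return Filtered [eeg_recording()] of identical shape.
#' @export
bandpass_filter <- function(rec, low = 0.1, high = 70) {
  if (high >= rec$fs / 2) {
    stop("high cutoff (", high, " Hz) must be below Nyquist (", rec$fs / 2,
         " Hz)")
  }
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  hp <- butter_coeffs(2, low, rec$fs, "high")
  lp <- butter_coeffs(4, high, rec$fs, "low")
  # low-pass first: the slow high-pass pole then only sees the already
  # band-limited signal, keeping its edge transient proportionally small
  rec <- apply_filter_rec(rec, lp$b, lp$a)
  apply_filter_rec(rec, hp$b, hp$a)
}

#' Notch filter a recording
#'
#' Zero-phase constrained biquad notch removing narrow-band mains
#' interference (default 50 Hz). The quality factor sets the -3 dB width to
#' `freq / q` Hz, so immediate neighbors (e.g. 45 and 55 Hz) pass nearly
#' unattenuated.
#'
#' @param rec An [eeg_recording()].
#' @param freq Notch center frequency in Hz; must be below Nyquist.
#' @param q Quality factor.
#' @return Filtered [eeg_recording()] of identical shape.
#' @export
notch_filter <- function(rec, freq = 50, q = 30) {
  if (freq >= rec$fs / 2) {
    stop("notch frequency (", freq, " Hz) must be below Nyquist (",
         rec$fs / 2, " Hz)")
  }
  w0 <- 2 * pi * freq / rec$fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  apply_filter_rec(rec, b, a)
}
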