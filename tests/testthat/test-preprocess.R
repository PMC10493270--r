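test_that("bandpass filter attenuates out-of-band and passes in-band (sweep oracle)", {
  hi <- sine_recording(100, fs = 250)
  out <- bandpass_filter(hi, 0.1, 70)
  expect_lt(rms(out$data), 0.1 * rms(hi$data))
  mid <- sine_recording(10, fs = 250)
  out2 <- bandpass_filter(mid, 0.1, 70)
  expect_lt(abs(rms(out2$data) - rms(mid$data)) / rms(mid$data), 0.05)
  z <- eeg_recording(matrix(0, 1, 2000), 250, "X")
  expect_equal(max(abs(bandpass_filter(z)$data)), 0)
  expect_error(bandpass_filter(sine_recording(10, 120), 0.1, 70), "Nyquist")
})

test_that("notch filter removes 50 Hz but spares 45/55 Hz", {
  x50 <- sine_recording(50, fs = 200)
  expect_lt(rms(notch_filter(x50)$data), 0.1 * rms(x50$data))
  x45 <- sine_recording(45, fs = 200)
  expect_lt(abs(rms(notch_filter(x45)$data) - rms(x45$data)) / rms(x45$data),
            0.3)
  x55 <- sine_recording(55, fs = 200)
  expect_lt(abs(rms(notch_filter(x55)$data) - rms(x55$data)) / rms(x55$data),
            0.3)
  z <- eeg_recording(matrix(0, 1, 2000), 200, "X")
  expect_equal(max(abs(notch_filter(z)$data)), 0)
  expect_error(notch_filter(sine_recording(10, 90), 50), "Nyquist")
})

test_that("average reference drops the ears and zeroes the cross-channel mean", {
  rec <- generate_recording(default_class_specs()$control, 60, 200, seed = 2)
  out <- average_reference(rec)
  expect_equal(nrow(out$data), 16)
  expect_setequal(out$channel_names, montage_scalp16())
  expect_lt(max(abs(colMeans(out$data))), 1e-9)
  # identical constant channels cancel entirely
  const <- eeg_recording(matrix(3.7, 18, 50), 200, montage_1020())
  expect_lt(max(abs(average_reference(const)$data)), 1e-12)
  short <- eeg_recording(matrix(0, 2, 50), 200, c("Fp1", "Fp2"))
  expect_error(average_reference(short), "montage error")
})

test_that("z-score normalization matches the population-std formula", {
  rec <- eeg_recording(matrix(c(1, 2, 3), 1), 100, "X", "s")
  out <- zscore(rec)
  expect_equal(as.numeric(out$data), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-7)                    # population std
  # idempotence on an already standardized channel
  out2 <- zscore(out)
  expect_lt(max(abs(out2$data - out$data)), 1e-9)
  # per-channel scope: each channel ends at mean 0, sd 1
  rec3 <- eeg_recording(matrix(rnorm(3 * 500, mean = 5, sd = 4), 3), 100,
                        c("a", "b", "c"))
  out3 <- zscore(rec3)
  expect_lt(max(abs(rowMeans(out3$data))), 1e-9)
  expect_lt(max(abs(sqrt(rowMeans(out3$data^2)) - 1)), 1e-6)
  flat <- eeg_recording(matrix(c(1, 1, 1, 0, 1, 2), 2, byrow = TRUE), 100,
                        c("f", "g"))
  expect_error(zscore(flat), "flat channel")
})

test_that("segmentation yields 60-s segments of twenty tiling 3-s pieces", {
  rec <- eeg_recording(matrix(rnorm(2 * 60 * 200), 2), 200, c("a", "b"))
  segs <- segment_recording(rec)
  expect_length(segs, 1)
  expect_length(segs[[1]]$piece_starts, 20)
  expect_equal(segs[[1]]$piece_len, 600)
  # pieces tile without gap or overlap
  expect_equal(segs[[1]]$piece_starts, seq(1, 60 * 200, by = 600))
  rec130 <- eeg_recording(matrix(rnorm(130 * 200), 1), 200, "a")
  expect_length(segment_recording(rec130), 2)       # 10 s remainder dropped
  rec59 <- eeg_recording(matrix(rnorm(59 * 200), 1), 200, "a")
  expect_warning(s59 <- segment_recording(rec59), "shorter")
  expect_length(s59, 0)
})

test_that("STFT power localizes tones, nulls silence and is flat on white noise", {
  fs <- 200
  t <- (seq_len(3 * fs) - 1) / fs
  p <- stft_power(sin(2 * pi * 10 * t), fs)
  freq <- attr(p, "freq")
  expect_equal(ncol(p), 5)                          # 1-s Hann, 50% overlap
  for (j in seq_len(ncol(p))) {
    expect_equal(freq[which.max(p[, j])], 10)
  }
  expect_true(all(stft_power(numeric(3 * fs), fs) == 0))
  set.seed(1)
  pw <- 0
  for (r in 1:20) pw <- pw + rowMeans(stft_power(rnorm(3 * fs), fs))
  mid <- pw[freq > 5 & freq < 90]
  expect_lt(max(mid) / min(mid), 2)                 # flat within 3 dB
  expect_error(stft_power(rnorm(100), fs, window_s = 1), "longer")
  expect_error(stft_power(rnorm(600), fs, overlap = 1), "overlap")
})

test_that("STFT matches a direct DFT evaluation on a single frame", {
  fs <- 16
  x <- rnorm(16)
  p <- stft_power(x, fs, window_s = 1, overlap = 0)
  nw <- 16
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nw - 1)) / nw)
  xw <- x * w
  dft <- vapply(0:(nw / 2), function(k) {
    abs(sum(xw * exp(-2i * pi * k * (0:(nw - 1)) / nw)))^2
  }, numeric(1))
  expected <- dft / (fs * sum(w^2))
  expected[2:(nw / 2)] <- 2 * expected[2:(nw / 2)]  # one-sided doubling
  expect_equal(as.numeric(p[, 1]), expected, tolerance = 1e-10)
})

test_that("CPD maps concatenate pieces along time and respect the frequency band", {
  rec <- generate_recording(default_class_specs()$nmdar, 60, 200, seed = 3)
  rec <- zscore(average_reference(rec))
  seg <- segment_recording(rec)[[1]]
  cpds <- build_cpd(seg)
  expect_length(cpds, 16)
  expect_equal(dim(cpds[[1]]$values), c(71, 100))   # 20 pieces x 5 frames
  expect_equal(ncol(cpds[[1]]$values) %% 20, 0)
  expect_true(all(cpds[[1]]$values >= 0))
  expect_equal(max(cpds[[1]]$freq), 70)
  expect_false(is.unsorted(cpds[[1]]$freq))
  # permuting the piece order permutes the CPD column blocks correspondingly
  perm <- c(2:20, 1)
  seg2 <- seg
  cols <- function(k) ((k - 1) * 600 + 1):(k * 600)
  for (k in seq_len(20)) seg2$data[, cols(k)] <- seg$data[, cols(perm[k])]
  cpd2 <- build_cpd(seg2)
  blocks <- function(v, k) v[, ((k - 1) * 5 + 1):(k * 5)]
  for (k in c(1, 7, 20)) {
    expect_equal(blocks(cpd2[[3]]$values, k),
                 blocks(cpds[[3]]$values, perm[k]), tolerance = 1e-12)
  }
})

test_that("the full preprocessing pipeline is deterministic and shaped per contract", {
  rec <- generate_recording(default_class_specs()$viral, 60, 200, seed = 8)
  a <- preprocess_recording(rec)
  b <- preprocess_recording(rec)
  expect_length(a, 1)
  expect_length(a[[1]], 16)
  expect_identical(a[[1]][[5]]$values, b[[1]][[5]]$values)
  expect_equal(a[[1]][[1]]$subject_id, rec$subject_id)
  expect_equal(a[[1]][[1]]$label, "viral")
})

test_that("resampling preserves band content", {
  rec <- sine_recording(10, fs = 250, dur = 4)
  out <- resample_recording(rec, 200)
  expect_equal(ncol(out$data), 800)
  sp <- stats::spec.pgram(stats::ts(out$data[1, ], frequency = 200),
                          plot = FALSE)
  expect_equal(sp$freq[which.max(sp$spec)], 10, tolerance = 0.3)
})
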