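#' Class labels of the classification task
#'
#' Three diagnostic groups: healthy controls, anti-NMDA-receptor (autoimmune)
#' encephalitis, and viral encephalitis.
#'
#' @return Character vector of the three class labels, in canonical order.
#' @export
class_labels <- function() c("control", "nmdar", "viral")

#' Spectral class specification for the synthetic generator
#'
#' Describes one diagnostic class as a sum of narrow-band oscillatory
#' components over a pink-noise background. Each component has a center
#' frequency (Hz), a frequency jitter half-width (Hz, realized per subject),
#' an amplitude (arbitrary microvolt scale), a burst duty cycle in \[0, 1\]
#' (1 = continuous), and optionally the index of another component whose
#' positive half-wave amplitude-modulates it (used to emulate the
#' "extreme delta brush" pattern: beta bursts riding on each delta wave).
#'
#' @param label One of [class_labels()].
#' @param components data.frame with columns `freq`, `bw`, `amp`, `duty`,
#'   `mod_by` (integer index into `components` or `NA`).
#' @param noise_amplitude Pink-noise scale (same units as `amp`).
#' @param spatial_profile Named numeric vector of per-electrode gains in
#'   \[0, 1\], covering every montage channel.
#' @return An object of class `class_spec`.
#' @export
class_spec <- function(label, components, noise_amplitude, spatial_profile) {
  stopifnot(is.data.frame(components),
            all(c("freq", "bw", "amp", "duty") %in% names(components)))
  if (is.null(components$mod_by)) components$mod_by <- NA_integer_
  if (any(components$amp < 0) || noise_amplitude < 0) {
    stop("amplitudes must be >= 0")
  }
  if (any(components$duty < 0 | components$duty > 1)) {
    stop("duty cycles must lie in [0, 1]")
  }
  if (any(unlist(spatial_profile) < 0) || any(unlist(spatial_profile) > 1)) {
    stop("spatial_profile gains must lie in [0, 1]")
  }
  structure(list(label = label, components = components,
                 noise_amplitude = noise_amplitude,
                 spatial_profile = unlist(spatial_profile)),
            class = "class_spec")
}

# Spatial gain helpers: named vectors over the full 18-channel montage.
spatial_uniform <- function(gain = 1, montage = montage_1020(), ears = 0.3) {
  g <- rep(gain, length(montage))
  names(g) <- montage
  g[names(g) %in% c("A1", "A2")] <- ears * gain
  g
}

spatial_posterior <- function(montage = montage_1020()) {
  g <- spatial_uniform(0.2, montage)
  g[names(g) %in% c("O1", "O2")] <- 1
  g[names(g) %in% c("P3", "P4", "T5", "T6")] <- 0.7
  g
}

#' Default class specifications
#'
#' Stand-in spectral signatures for the three groups (the clinical cohort
#' they emulate is not public, and no quantitative spectral parameters are
#' available; see the methods vignette):
#' \itemize{
#'   \item control - posterior-dominant ~10 Hz alpha rhythm over pink noise;
#'   \item viral - diffuse high-amplitude 2-4 Hz (3 Hz center) slowing;
#'   \item nmdar - diffuse delta (2.5 Hz) with superimposed beta (25 Hz)
#'     bursts amplitude-modulated by the delta wave ("extreme delta brush").
#' }
#' All classes share a common background (pink noise plus a weak posterior
#' alpha). `separation` linearly scales the class-distinctive component
#' amplitudes: at 1 the classes are fully expressed, at 0 all three classes
#' collapse onto the shared background and are indistinguishable.
#'
#' @param separation Class-separation multiplier in \[0, 1\].
#' @return Named list of three `class_spec` objects.
#' @export
default_class_specs <- function(separation = 1) {
  stopifnot(separation >= 0, separation <= 1)
  s <- separation
  base_alpha <- data.frame(freq = 10, bw = 0.5, amp = 8, duty = 1,
                           mod_by = NA_integer_)
  comp <- function(...) {
    data.frame(..., stringsAsFactors = FALSE)
  }
  control <- rbind(
    base_alpha,
    comp(freq = 10, bw = 0.5, amp = 14 * s, duty = 1, mod_by = NA_integer_)
  )
  viral <- rbind(
    base_alpha,
    comp(freq = 3.2, bw = 0.8, amp = 40 * s, duty = 1, mod_by = NA_integer_)
  )
  nmdar <- rbind(
    base_alpha,
    comp(freq = 2, bw = 0.3, amp = 30 * s, duty = 1, mod_by = NA_integer_),
    # beta rides the positive half of each delta wave -> effective duty ~0.5
    comp(freq = 25, bw = 2, amp = 25 * s, duty = 1, mod_by = 2L)
  )
  list(
    control = class_spec("control", control, 10, spatial_posterior()),
    nmdar   = class_spec("nmdar", nmdar, 10, spatial_uniform(1)),
    viral   = class_spec("viral", viral, 10, spatial_uniform(1))
  )
}

#' Cohort specification
#'
#' @param n_subjects_per_class Subjects per diagnostic class (>= 1).
#' @param duration_s Recording length in seconds (>= 60, so that at least one
#'   60-s segment exists).
#' @param fs Sampling rate in Hz (> 140, i.e. twice the 70 Hz filter edge).
#' @param seed Master RNG seed for the cohort.
#' @param montage Ordered channel-name list; must contain the 18 acquisition
#'   channels.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects_per_class, duration_s = 60, fs = 200,
                        seed = 1, montage = montage_1020()) {
  if (n_subjects_per_class < 1) stop("n_subjects_per_class must be >= 1")
  if (duration_s < 60) stop("duration_s must be >= 60 (one 60-s segment)")
  if (fs <= 140) stop("fs must exceed 140 Hz (2 x 70 Hz filter edge)")
  missing <- setdiff(montage_1020(), montage)
  if (length(missing)) {
    stop("montage lacks required channels: ", paste(missing, collapse = ", "))
  }
  structure(list(n_subjects_per_class = n_subjects_per_class,
                 duration_s = duration_s, fs = fs, seed = seed,
                 montage = montage),
            class = "cohort_spec")
}

# Pink (1/f amplitude) noise via spectral shaping of white Gaussian noise.
pink_noise <- function(n, amp = 1) {
  if (amp == 0) return(numeric(n))
  w <- rnorm(n)
  W <- fft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)            # symmetric frequency index
  scale <- ifelse(f == 0, 0, 1 / sqrt(f))
  x <- Re(fft(W * scale, inverse = TRUE)) / n
  amp * x / stats::sd(x)
}

# Smoothed periodic on/off envelope with the given duty cycle (period 2 s).
burst_envelope <- function(t, duty, ramp_s = 0.1) {
  if (duty >= 1) return(rep(1, length(t)))
  if (duty <= 0) return(rep(0, length(t)))
  period <- 2
  phase <- (t %% period) / period
  env <- as.numeric(phase < duty)
  # raised-cosine smoothing of the edges to avoid broadband clicks
  n_ramp <- max(1L, round(ramp_s * length(t) / max(t[length(t)], 1)))
  kern <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_ramp) / (n_ramp + 1))
  kern <- kern / sum(kern)
  as.numeric(stats::filter(env, kern, sides = 2, circular = TRUE))
}

#' Generate one synthetic EEG recording
#'
#' Synthesizes a channels-by-samples matrix by summing, per channel, the
#' class's oscillatory components (with per-subject gain and frequency
#' jitter) scaled by the electrode's spatial-profile gain, plus independent
#' pink noise. Deterministic given `seed`.
#'
#' @param spec A [class_spec()].
#' @param duration_s Length in seconds.
#' @param fs Sampling rate in Hz.
#' @param montage Channel-name vector; every name must appear in
#'   `spec$spatial_profile`.
#' @param subject_id Subject identifier stored on the recording.
#' @param seed RNG seed.
#' @return An [eeg_recording()] with `len(montage)` x `round(duration_s*fs)`
#'   data.
#' @export
generate_recording <- function(spec, duration_s, fs, montage = montage_1020(),
                               subject_id = "S1", seed = 1) {
  if (fs <= 140) stop("fs must exceed 140 Hz (sampling error)")
  if (duration_s < 60) stop("duration_s must be >= 60")
  missing <- setdiff(montage, names(spec$spatial_profile))
  if (length(missing)) {
    stop("spatial_profile lacks montage channel(s): ",
         paste(missing, collapse = ", "))
  }
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  nch <- length(montage)
  with_seed(seed, {
    # per-subject variability: one gain and frequency jitter per component
    comps <- spec$components
    k <- nrow(comps)
    gain <- if (k) runif(k, 0.8, 1.2) else numeric(0)
    fjit <- if (k) runif(k, -1, 1) * comps$bw else numeric(0)
    phase0 <- if (k) runif(k, 0, 2 * pi) else numeric(0)
    # spatial heterogeneity: per-channel gain and phase variation around the
    # profile, so that oscillations are not common-mode (a perfectly
    # coherent uniform rhythm would vanish under the average reference)
    ch_gain <- matrix(runif(nch * max(k, 1), 0.75, 1.25), nch)
    ch_phase <- matrix(runif(nch * max(k, 1), -0.6, 0.6), nch)
    envs <- lapply(seq_len(k), function(i) burst_envelope(t, comps$duty[i]))
    data <- matrix(0, nrow = nch, ncol = n, dimnames = list(montage, NULL))
    for (ch in seq_len(nch)) {
      g_sp <- spec$spatial_profile[[montage[ch]]]
      sig <- numeric(n)
      if (k) {
        waves <- matrix(0, nrow = k, ncol = n)
        for (i in seq_len(k)) {
          f_i <- max(comps$freq[i] + fjit[i], 0.1)
          waves[i, ] <- gain[i] * ch_gain[ch, i] * comps$amp[i] * envs[[i]] *
            sin(2 * pi * f_i * t + phase0[i] + ch_phase[ch, i])
        }
        for (i in seq_len(k)) {  # amplitude modulation by another component
          m <- comps$mod_by[i]
          if (!is.na(m)) {
            carrier <- waves[m, ]
            mx <- max(abs(carrier))
            if (mx > 0) waves[i, ] <- waves[i, ] * pmax(carrier / mx, 0)
          }
        }
        sig <- g_sp * colSums(waves)
      }
      data[ch, ] <- sig + pink_noise(n, spec$noise_amplitude)
    }
    eeg_recording(data, fs, montage, subject_id, spec$label)
  })
}

#' Generate a labeled synthetic cohort
#'
#' @param cohort A [cohort_spec()].
#' @param class_specs Named list of three [class_spec()] objects (one per
#'   label in [class_labels()]); defaults to [default_class_specs()].
#' @return List of [eeg_recording()] objects, `3 * n_subjects_per_class`
#'   long, with unique subject IDs and balanced labels.
#' @export
generate_cohort <- function(cohort, class_specs = default_class_specs()) {
  stopifnot(inherits(cohort, "cohort_spec"))
  labs <- class_labels()
  if (!all(labs %in% names(class_specs))) {
    stop("class_specs must be named with: ", paste(labs, collapse = ", "))
  }
  recs <- list()
  idx <- 0
  for (lab in labs) {
    for (s in seq_len(cohort$n_subjects_per_class)) {
      idx <- idx + 1
      sid <- sprintf("%s_%02d", lab, s)
      recs[[idx]] <- generate_recording(
        class_specs[[lab]], cohort$duration_s, cohort$fs, cohort$montage,
        subject_id = sid, seed = derive_seed(cohort$seed, match(lab, labs), s)
      )
    }
  }
  recs
}
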