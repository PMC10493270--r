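# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures.

# Direct evaluation of scaled dot-product attention softmax(Q K^T / sqrt(dk)) V,
# written independently of the package implementation.
sdp_attention <- function(Q, K, V) {
  S <- Q %*% t(K) / sqrt(ncol(K))
  W <- t(apply(S, 1, function(r) {
    e <- exp(r - max(r))
    e / sum(e)
  }))
  W %*% V
}

# Dense-matrix oracle for one graph convolution on an explicit adjacency.
dense_gcn_oracle <- function(A, H, W) {
  Ah <- A + diag(nrow(A))
  d <- rowSums(Ah)
  An <- diag(1 / sqrt(d)) %*% Ah %*% diag(1 / sqrt(d))
  An %*% H %*% W
}

# A small transformer configuration for fast tests.
tiny_ttm_cfg <- function(n_classes = 3, mask = TRUE) {
  ttm_config(input_dim = c(12, 10), patch = 4, embed_dim = 8, depth = 2,
             n_heads = 2, mlp_ratio = 2, n_classes = n_classes, mask = mask)
}

# Synthetic, linearly separable cpd_dataset built directly (no
# preprocessing): one "segment" per subject, 16 channel maps each, class k
# marked by an additive bump in a class-specific row band.
make_tiny_cpd_dataset <- function(n_per_class = 4, input_dim = c(12, 10),
                                  seed = 42, classes = class_labels(),
                                  strength = 3) {
  set.seed(seed)
  inputs <- list()
  meta <- list()
  chans <- montage_scalp16()
  for (ci in seq_along(classes)) {
    for (s in seq_len(n_per_class)) {
      sid <- sprintf("%s_%02d", classes[ci], s)
      for (ch in chans) {
        m <- matrix(rnorm(prod(input_dim)), input_dim[1], input_dim[2])
        rows <- ((ci - 1) * 4 + 1):(ci * 4)
        m[rows, ] <- m[rows, ] + strength
        inputs[[length(inputs) + 1]] <- m
        meta[[length(meta) + 1]] <- data.frame(
          subject_id = sid, label = classes[ci], segment = 1L, channel = ch,
          segment_key = paste0(sid, "#1"), stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(inputs = inputs, meta = do.call(rbind, meta),
                 input_dim = input_dim),
            class = "cpd_dataset")
}

# Single-channel recording helper for filter tests. Long enough that
# zero-phase edge transients are a negligible share of the signal, as in
# clinical recordings.
sine_recording <- function(freq, fs, dur = 30, amp = 1) {
  t <- (seq_len(dur * fs) - 1) / fs
  eeg_recording(matrix(amp * sin(2 * pi * freq * t), 1), fs, "X")
}

rms <- function(x) sqrt(mean(x^2))
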