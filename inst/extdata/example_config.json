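{
  "seed": 1,
  "outdir": "scalpnet_run",
  "simulate": {
    "n_subjects_per_class": 12,
    "duration_s": 60,
    "fs": 200,
    "separation": 1.0
  },
  "preprocess": {
    "fs": 200,
    "bandpass_low": 0.1,
    "bandpass_high": 70,
    "notch_freq": 50,
    "segment_s": 60,
    "piece_s": 3,
    "stft_window_s": 1,
    "stft_overlap": 0.5,
    "fmax": 70
  },
  "model": {
    "ttm": { "patch": 8, "embed_dim": 64, "depth": 4, "n_heads": 4, "mlp_ratio": 2 },
    "sgcm": { "n_layers": 2, "hidden_dim": 64 }
  },
  "train": { "profile": "reduced", "batch_size": 32 },
  "experiment": {
    "classes": ["control", "nmdar", "viral"],
    "k": 10,
    "folds": [1],
    "pairwise": false
  }
}
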