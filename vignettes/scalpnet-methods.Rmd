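---
title: "Classifying encephalitis from EEG spectrograms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying encephalitis from EEG spectrograms: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Anti-NMDA-receptor encephalitis is a rare autoimmune disease whose EEG can
show a characteristic "extreme delta brush" (EDB): rhythmic delta slow waves
with superimposed fast (beta) activity. Viral encephalitis typically shows
diffuse high-amplitude slowing, while healthy awake children show a
posterior-dominant ~10 Hz alpha rhythm. `scalpnet` implements a two-stage
deep pipeline that classifies awake resting-state scalp EEG into these three
groups, and a synthetic cohort generator that emulates the three spectral
signatures so that every stage is testable without clinical data.

## Pipeline

1. **Preprocessing.** Recordings on the 18-channel clinical 10-20 montage
   (16 scalp electrodes plus ears A1/A2) are resampled to a common rate
   (default 200 Hz), band-pass filtered 0.1-70 Hz, notch filtered at 50 Hz,
   optionally stripped of user-listed ICA components, re-referenced to the
   common average of the 16 scalp channels (A1/A2 dropped), and z-scored per
   channel with the population standard deviation, `X* = (X - mu)/delta`.
   Each recording is cut into non-overlapping 60-s segments of twenty 3-s
   pieces. Each piece is turned into a Hann-window STFT power map and the
   twenty maps are concatenated along time into one *concatenated power
   density* (CPD) map per channel per segment - a 71 x 100 image with the
   defaults (1-s window, 50 % overlap, frequency axis truncated at 70 Hz).

2. **Stage 1 - temporal transformer (TTM).** A small-data vision
   transformer classifies single-channel CPD maps. *Shifted Patch
   Tokenization* concatenates the image with four half-patch diagonal
   shifts before 8 x 8 patch embedding; *Locality Self-Attention* masks the
   diagonal of the attention score matrix to -Inf and replaces the fixed
   `sqrt(d_k)` softmax scale with a learnable per-head temperature
   initialized at `sqrt(d_k)`. Blocks are pre-norm with GELU MLPs.
   One shared-weight TTM is trained on all channels' maps; per-channel test
   accuracy is reported afterwards.

3. **Stage 2 - spatial graph convolution (SGCM).** The trained TTM is
   frozen; its final-layer-norm class-token embedding of each of the 16
   channel maps becomes a node feature on the scalp-electrode graph. The
   graph has binary adjacency `A` (1 iff two electrodes are connected),
   self-loops added (`A_hat = A + I`), and the symmetric normalization
   `A_norm = D_hat^{-1/2} A_hat D_hat^{-1/2}`. Each layer computes
   `H^{(l+1)} = sigma(A_norm H^{(l)} W^{(l)})`; mean pooling over nodes and
   a linear head produce segment-level logits.

4. **Evaluation.** Subject-wise 10-fold cross-validation (all of a
   subject's segments share a fold), accuracy / recall / precision / F1
   (binary formulas for two classes; macro-averaged one-vs-rest values
   otherwise), confusion matrices summed over folds, metrics averaged over
   folds, and per-class one-vs-rest Mann-Whitney AUC.

Both stages train with ADAM at learning rate 1e-4 under cross-entropy:
150 epochs for stage 1 and 80 for stage 2 at full scale.

## The synthetic cohort: what it emulates, and what it does not

No public recordings exist for this task, and no quantitative spectral
parameters of the clinical classes are available; the generator's defaults
are explicit stand-ins, chosen once to look like textbook awake resting
EEG:

* **control** - posterior-dominant 10 Hz alpha (occipital gain 1, parietal
  0.7, elsewhere 0.2) over pink noise;
* **viral** - diffuse high-amplitude ~3.2 Hz slowing;
* **nmdar** - diffuse ~2 Hz delta with 25 Hz beta bursts whose envelope is
  the positive half of the delta wave (duty cycle ~0.5), emulating EDB.

All classes share a pink-noise background (amplitude 10 on the same
arbitrary microvolt scale) and a weak posterior alpha, so class information
is spectral, not trivial amplitude. Per subject, every component receives a
random gain (+/-20 %) and frequency jitter (within its bandwidth), so
subject-wise cross-validation is meaningful. Per channel, each component
additionally receives gain (+/-25 %) and phase (+/-0.6 rad) variation: a
perfectly coherent, spatially uniform rhythm is common-mode and would be
annihilated by the average reference, which no physical EEG is. The
`separation` parameter scales the class-distinctive amplitudes linearly; at
0 the three classes collapse onto the shared background.

The generator is *not* forward-modeled EEG: there is no head geometry, no
volume conduction, no artifacts, no non-stationarity beyond burst
envelopes. A green end-to-end test therefore establishes that the pipeline
recovers planted, well-separated spectral structure through the full
preprocessing/transformer/graph stack - not that it would reach any
particular accuracy on clinical data.

## Numerical and design choices

* **Printed normalization of the graph rule.** The source formulation
  prints the propagation rule with a `D_hat^{1/2} ... D_hat^{-1/2}`
  normalization; that form is not a valid symmetric normalization, and the
  cited spectral-GCN rule is `D_hat^{-1/2} A_hat D_hat^{-1/2}`. The
  standard form is implemented.
* **Electrode adjacency.** The exact reference edge set is not recoverable,
  so the default connects electrodes within 1.0 rad great-circle distance
  on standard unit-sphere 10-20 coordinates (28 edges, minimum degree 3).
  Any two-column edge list can be dropped in.
* **Z-score scope.** Per channel over the whole recording, with the
  population (1/n) standard deviation; preserves inter-channel topography.
* **CPD model input.** `log10(power + 1e-12)`, then per-map
  standardization: spectrogram dynamic range spans orders of magnitude and
  transformer inputs need bounded scale.
* **Filters.** Butterworth designs via bilinear transform (order-4 low-pass
  at 70 Hz, order-2 high-pass at 0.1 Hz, applied low-pass first) and a
  Q = 30 biquad notch, all run forward-backward (zero phase) with
  even-reflection padding and steady-state initial conditions. The low-pass
  runs before the high-pass so the 0.1 Hz pole's edge transient is driven
  only by the band-limited signal.
* **Zero-initialized classifier heads.** Both stage heads start at zero.
  With short training schedules at the fixed 1e-4 learning rate, an
  argmax must not have to climb over random-init logit noise; a zero head
  makes predictions follow the accumulated (prototype-like) class signal
  from the first step. This is standard practice in fine-tuning and costs
  nothing at full scale.
* **Reduced profile.** Tests and scaled demonstrations use 15/8 epochs and
  batch size 8 (`train_config(profile = "reduced")`). The batch is shrunk
  along with the epochs because cohorts at desk scale have tens of
  segments: at batch 32 stage 2 would take ~8 optimizer steps total, an
  optimizer regime the full-scale procedure (thousands of steps) never
  enters. Full-scale defaults remain 150/80 epochs at batch 32.
* **ICA.** Component *selection* is expert work in the source procedure and
  is deliberately not automated: `apply_component_exclusion()` takes a
  user-supplied index list (empty list = identity). The decomposition is
  FastICA (symmetric, tanh contrast).
* **Degenerate inputs.** Flat channels make the z-score refuse rather than
  emit NaN; recordings shorter than 60 s yield zero segments with a
  warning; masked self-attention on a single token is an error (the
  all--Inf row is undefined); a class never predicted gets precision 0 by
  convention.
* **Determinism.** Every random choice (cohort, initialization, shuffling,
  fold assignment) derives from one master seed; repeated runs are
  bit-identical. Model forward passes have no stochastic layers.

## Scaled-down evaluation

The packaged acceptance checks run the full two-stage pipeline on seeded
synthetic cohorts that are deliberately small (12 subjects per class for
the recovery check, evaluating 2 of the 10 subject-wise folds; 6 subjects
per class across three separation settings for the degradation check) so
the whole suite fits a single-CPU time budget. These scale-downs trade
statistical resolution, not procedure: every stage runs exactly as at full
scale.

## Known limitations

* Transformer and graph hyperparameters (depth 4, width 64, 4 heads, patch
  8; L = 2 graph layers) are defaults chosen for the small-data regime; the
  reference hyperparameters are not published, so published accuracies are
  not reproducible even in principle from this package.
* The EDF reader supports continuous recordings with a common sampling rate
  across signals (the format the writer emits); EDF+ annotations are
  ignored.
* Attention is O(T^2) per map; with much longer segments or finer STFT
  hops, token counts grow quickly.
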