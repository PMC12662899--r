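---
title: "Automatic segmentation of swallowing sounds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic segmentation of swallowing sounds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cervical auscultation (CA) records the sounds of swallowing from a
microphone placed on the neck. A clinically useful automatic system must
take a raw one-minute feeding recording and return time-stamped swallow
events, without an expert manually segmenting the audio first. This
package implements a transfer-learning pipeline for that task: a fixed
acoustic front end and pretrained-style embedding stage, a small trainable
fully-connected head that predicts swallow occupancy at sub-second
resolution, and an overlap-add decoder that turns per-frame predictions
into event intervals.

## Pipeline model

1. **Audio conditioning.** Input WAV audio (any rate, any channel count)
   is averaged to mono, resampled to 16 kHz with a polyphase band-limited
   converter, and peak-normalized to [-1, 1].
2. **Framing.** The recording is cut into 0.96 s frames with 50% overlap
   (hop 0.48 s, 15360 samples per frame at 16 kHz); the final partial
   frame is zero-padded so swallows at the tail of a recording remain
   detectable.
3. **Front end.** Each frame becomes a 96 x 64 log-Mel patch: 25 ms
   periodic-Hann STFT windows with a 10 ms hop, magnitude spectra pooled
   onto 64 triangular mel bands over 125–7500 Hz, compressed as
   `log(energy + 0.001)`. These parameters follow the published front-end
   convention of the pretrained audio classification network whose
   embeddings the backend contract emulates. A scalar zero-crossing rate
   (fraction of consecutive-sample sign changes, zeros counted positive)
   is computed per frame from the raw waveform.
4. **Embedding.** A pluggable backend maps each patch to a fixed-length
   vector (1024 by default); the ZCR scalar is appended to the embedding
   — not to the log-Mel input — giving a 1025-dim feature vector.
5. **Prediction head.** A fully-connected network (hidden layers of 1024,
   1024 and 512 ReLU units; a 6-unit sigmoid output) maps the feature
   vector to six confidences, one per 0.16 s subframe of the frame.
   Ground-truth labels mark a subframe 1 when at least half of it (0.08 s)
   overlaps annotated swallow time.
6. **Decoding.** Subframe confidences from overlapping frames are
   overlap-added onto a recording-wide 0.16 s slot grid together with a
   coverage count; the coverage-normalized mean is thresholded at
   `tau = 0.5` (ties to 1) and maximal runs of active slots become
   predicted events. All event boundaries are multiples of 0.16 s, the
   decoder's temporal resolution.
7. **Evaluation.** A ground-truth swallow counts as detected when at
   least 30% of its duration is covered by the union of predicted events
   (inclusive, so fragmented detections jointly covering 30% count).
   Alongside this event-level view the package reports a slot-wise
   subframe confusion matrix with PPV, NPV, specificity, sensitivity and
   F1 for both classes plus overall accuracy; metrics with zero
   denominators are `NA`, never zero.

## Training procedure

Training operates on participant-labelled frame datasets. Participants —
never individual frames — are split 80/20 into training and validation
groups, making patient leakage structurally impossible. Before every
epoch the training frames are re-balanced (frames containing any swallow
subframe vs. all-zero frames, equalized by undersampling the majority
group without replacement) and re-shuffled under an epoch-specific seed.
Optimization is mini-batch Adam (batch 32, learning rate 1e-3) on mean
squared error against the six binary labels, with L2 (coefficient 1e-4)
on the first two hidden layers' weights only, for at most 100 epochs.
The weights from the epoch with the lowest validation loss are kept, and
training stops early after 10 epochs without improvement. Every run is
bit-reproducible given the configuration seed.

Two numerical choices matter in practice, and both are this package's
own (the training recipe above does not determine them):

* **Feature standardization.** Per-feature mean/sd are fitted on the
  unbalanced training set, stored in the model artifact, and applied at
  prediction time. Without it the MSE-plus-sigmoid objective starts deep
  in its saturated region and training collapses to a constant predictor.
* **Output-layer initialization.** Hidden layers use fan-in-scaled (He)
  initialization; the sigmoid output layer starts with near-zero weights
  so initial predictions sit at 0.5, where the MSE gradient through the
  sigmoid is largest.

## The embedding backend contract

The head only ever sees `(embedding, zcr)` vectors, so any deterministic
fixed-dimension backend slots into the pipeline unchanged. The `yamnet`
adapter slot exposes the published pretrained network's 1024-dim
penultimate embeddings but requires an external model download and a
deep-learning runtime, so constructing it here raises an informative
error; it exists so a user with those resources can swap it in without
touching anything downstream.

The tested, default backend is `mel-stats`: per-band means of the
log-Mel patch over six 16-step temporal blocks (aligned with the six
0.16 s subframes) plus per-band standard deviation, minimum and maximum
over all 96 steps — 576 summary values — projected to 1024 dimensions by
a random Gaussian map drawn once from a fixed recorded seed, so artifacts
reproduce across machines. The temporal blocks are essential: a summary
using only whole-patch statistics is permutation-invariant over time, and
a head fed such features provably cannot assign a swallow to a subframe —
its best prediction is the frame's overall occupancy, which leaves short
events (under roughly half a frame) undetectable at `tau = 0.5`. Block
means preserve where in the frame energy occurs while staying
deterministic and dependency-free.

Before embedding, `featurize_recording()` subtracts each mel band's
recording-level mean from the patches (channel mean normalization, a
standard robustness step in sound-event detection). This removes the
recording's background spectral colour and gain, which is what lets a
head trained under one background profile transfer to recordings made
under another; without it a shifted test background pushes features far
outside the training distribution and detections vanish.

## The synthetic-data generator

No clinical recordings ship with the package, so every stage is
exercised on a built-in simulator of one-minute CA recordings:

* background: coloured noise (amplitude ∝ f^-0.5, i.e. pink, by
  default) at a fixed reference level;
* swallows: 5–20 per recording (drawn per seed), 0.3–0.9 s long, at
  least 0.5 s apart; each is 2–3 band-limited (300–3000 Hz) noise bursts
  with exponential-decay envelopes, scaled so the mean 300–3000 Hz band
  power inside swallow intervals sits 10 dB above background;
* distractors (absent from the gold annotations, never overlapping
  swallows): tonal hums at 200–500 Hz and single loud clicks, about two
  per minute.

Cohorts are written as one 16-bit WAV plus one events CSV per synthetic
participant with a JSON manifest of roles and seeds. The test cohort can
follow a shifted background profile — spectral exponent 1.0 instead of
0.5 and +3 dB — emulating the domain mismatch of training on recordings
from one acquisition setup and testing on another.

The swallow surrogate is a separability construct, not clinical realism:
real swallow acoustics are variable, overlap spectrally with ambient
noise, and co-occur with breath and vocal sounds the simulator omits.
Passing the synthetic study therefore demonstrates that the pipeline's
mechanics (framing, labelling, learning, decoding, scoring) are correct
and that the end-to-end system detects separable events robustly across
a background shift — not that clinical-grade accuracy is attained.

## Problem sizes and defaults

The bundled end-to-end study uses 10 training-cohort participants (split
8/2) plus 4 test participants of 60 s each, three seeds, with the default
head configuration; one training run converges in roughly 20–35 epochs
under early stopping. Key tunables and their defaults: `tau = 0.5`
(decision threshold on the coverage-normalized timeline; the mean rather
than the raw sum is thresholded so one value of `tau` is meaningful both
at recording edges, coverage 1, and in the interior, coverage 2);
`min_overlap_frac = 0.30` (event-match rule, inclusive);
`min_duration_s = 0` and `merge_gap_s = 0` (decoder postprocessing off:
emitted segments are raw, though both knobs are exposed for
duration-prior or refractory-period heuristics); labelling occupancy
threshold 0.08 s (half a subframe — symmetric, suppresses sliver labels,
bounds boundary error at one slot per edge).

## Degenerate inputs and tie-breaks

All-zero audio normalizes to itself; empty event lists are valid
everywhere; a training set whose frames are all swallow or all
non-swallow is rejected as degenerate by the balancer; metrics with empty
denominators are reported as `NA`; slots never covered by any frame
threshold to 0; equality at any threshold (`>=` in labelling, matching
and thresholding) resolves toward the positive class.

## Known limitations

* The `mel-stats` backend is a stand-in contract implementation: its
  absolute performance says nothing about pretrained-network embeddings,
  only that the surrounding pipeline is sound.
* Event durations shorter than one slot (0.16 s) cannot be represented
  in the decoder output, and boundary accuracy is limited to one slot.
* The evaluation follows the at-least-30%-coverage convention; systems
  tuned under different matching rules are not directly comparable.
* Training on one CPU takes about a minute per cohort at the bundled
  problem size; the head is small by deep-learning standards but the
  1025-dim input layer dominates the cost.
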