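---
title: "Beat images, compact CNNs, and exact streaming accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beat images, compact CNNs, and exact streaming accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its own methods: the model and its
assumptions, the tunable parameters, the synthetic data the tests run on,
the numerical choices, and the limits of what the test suite shows.

## The problem

Ambulatory heart monitoring needs beat-level arrhythmia classification that
runs continuously on modest hardware. `ecgbeats` implements a pipeline for
that setting: annotated ECG in, per-beat class labels and confidences out,
with a streaming mode that accounts exactly for the samples a busy
classifier never sees.

The class vocabulary is fixed at 15 symbols: fourteen beat classes — normal
(N), left/right bundle branch block (L, R), premature ventricular
contraction (V), atrial premature (A), fusion of paced and normal (f),
fusion of ventricular and normal (F), junctional escape (j), aberrated
atrial premature (a), ventricular escape (E), junctional premature (J),
unclassifiable (Q), atrial escape (e), supraventricular premature (S) — and
one pooled non-beat symbol, Z. Grouping every non-beat annotation (rhythm
changes, noise markers, waveform boundaries, comments) into Z keeps the
target set small while leaving non-beat windows as a class the model can
learn to reject. Beat symbols outside the named set (for example paced
beats, `/`) map to Q, the declared catch-all beat class; the full
raw-to-grouped table ships as plain text in `inst/extdata/annotation_groups.txt`.
A standard-compliant beat flag decides beat vs. non-beat for raw symbols,
since the vocabulary alone does not.

## From signal to image

**Windows.** For image width $n$ (even), each annotated sample $x$ yields
the window $[x - n/2, x + n/2)$. Windows that would overrun either end of
the record are discarded — the annotation is skipped, not padded — so every
window has exactly $n$ samples with the annotated sample at 0-based offset
$n/2$.

**Skew.** Real beat detectors are not perfectly centered. The *skewed*
dataset variant re-cuts each window at $x + \delta$ with $\delta$ drawn
uniformly from the integers in $[-\lfloor n/4\rfloor, +\lfloor n/4\rfloor]$.
Uniformity is an assumption (the distribution is otherwise unspecified);
the test suite checks it with a $\chi^2$ test over 10,000 draws. Near record
boundaries the offset is redrawn a bounded number of times, then falls back
to 0 — a deliberate bias toward keeping the window rather than losing the
beat.

**Quantization.** Column $c$ of the image lights the single pixel at row
$$ r = \left\lfloor \frac{w_c - \text{min}}{d}\, h \right\rfloor, \qquad
   d = \text{max} - \text{min}, $$
clamped to $[0, h-1]$. Three choices here were genuinely open:

* *Clamping:* the bare formula yields $r = h$ when $w_c$ equals the maximum
  limit, and rows outside the raster for out-of-range samples. Clamping to
  $[0, h-1]$ preserves the one-lit-pixel-per-column invariant for every
  input, which downstream code relies on.
* *Offset by the minimum:* with a zero minimum the formula reduces to
  $\lfloor w_c/d \cdot h\rfloor$; subtracting the minimum first makes
  nonzero lower limits work without changing the zero-minimum case.
* *Limits are configuration, not per-window statistics.* Defaults are the
  analyzed channel's global min/max per record. Normalizing each window by
  its own range would destroy amplitude information that distinguishes beat
  classes (a ventricular ectopic is, among other things, *bigger*).

Row 0 is the minimum-amplitude row, so plotted naively the images are upside
down relative to a clinician's trace; they are kept that way, since only the
network consumes them. `image_to_signal()` decodes a raster back to cell
midpoints — a pure testing aid that bounds the quantization error at $d/h$
per sample.

**Datasets.** Windows from all records are pooled, shuffled with a stated
seed, and split 9:1 into train/test. The split is a global shuffle rather
than per-record, and no class balancing is applied. On-disk form: 8-bit
grayscale PNGs plus a CSV manifest (record, center index, skew offset,
label, split, limits).

## The classifiers

Two architectures are provided, both ending in a 15-way softmax:

* **proposed** — input (180, 64, 1); Conv 8@6×6 → pool → Conv 16@5×5 → pool
  → Conv 32@4×4 → pool → flatten → Dense 512 → 256 → 128 → 15. About 3.06 M
  parameters, the large majority in the first dense layer.
* **baseline** — input (128, 128, 1); three blocks of two batch-normalized
  3×3 convolutions (8, 16, 32 filters) each followed by pooling; then
  Dense 512 with batch normalization and the output layer. The published
  table this follows lists a max-pooling step *after* the flat dense layer,
  which is undefined on a vector; it is represented as an explicit, flagged
  no-op layer rather than silently dropped, and the surrounding stack is
  kept as printed.

Choices the architecture tables leave open, fixed here and exposed as code
rather than config ceremony: pooling is 2×2 with stride 2 and valid padding;
convolutions use "same" padding (TensorFlow convention, `pad_before =
floor((k-1)/2)`), which is what keeps three pool stages feasible on a
64-pixel-high input (64 → 32 → 16 → 8, width 180 → 90 → 45 → 22). The
optimizer is Adam at learning rate $10^{-3}$ with categorical cross-entropy
— the standard recipe for this architecture family; nothing in the package
depends on that choice beyond `train_cnn()`'s arguments. Batch size defaults
to 512. No class weighting is applied.

The engine itself (im2col convolution with BLAS matrix products, max-pool
argmax caching, batch-norm train/inference modes with running statistics,
Adam) is implemented in the package with RcppArmadillo; its backward pass is
verified against numeric differentiation in the test suite, with biases
jittered off zero because finite differences are one-sided at the ReLU kink.
All randomness (weight init, shuffling, skew) flows through R's RNG, so a
seed reproduces a fit exactly on a given BLAS.

## Metrics

Accuracy is trace over total of the 15×15 confusion matrix. Precision,
sensitivity and specificity are computed one-vs-rest per class and averaged.
The averaging convention is genuinely underdetermined in this setting, so
both are implemented: macro (default) averages over classes present in the
true labels, skipping classes with a zero denominator rather than scoring
them 0 — a small test split should not be penalized for classes it never
contained; micro pools the counts first. The defaults reproduce the
definitional hand-computed values in the tests (e.g. the 2-class matrix
[[8,2],[1,9]] gives accuracy 0.85 and macro sensitivity 0.85).

## The streaming workflow

The simulator pushes one sample every `period_factor / fs` seconds into a
ring buffer of size $n$; a full buffer evicts its oldest sample. The factor
defaults to 0.9 — the period is *shortened* by 10% to offset scheduling
overhead that would otherwise stretch a 30 s replay to ~33 s. The detector
loop: wait for a full buffer; copy it (the detector never reads the live
buffer mid-task); optionally check the copy for a centered beat; convert to
an image; classify; record the result together with the number of samples
pushed during the busy period; repeat until the source is exhausted.

*Center check.* "A beat near the center" is operationalized as: the sample
of maximum absolute deviation from the window median must lie within
$\pm\lfloor n/8\rfloor$ of $n/2$. Ties in the argmax break toward the lowest
index, so a flat window deterministically rejects (its "peak" is index 0,
far off-center for any realistic $n$). The tolerance is a parameter, and a
stub classifier can replace the network entirely, so alternative R-peak
detectors can be evaluated in place.

*Virtual time.* In virtual-time mode, stage costs are supplied in sample
periods and a logical clock replaces sleeping. The accounting is then exact:
a classifier costing $k$ periods misses exactly $k$ samples per
classification, which the acceptance tests assert literally. Wall-clock mode
exists and measures real stage timings, but no test asserts them —
wall-clock numbers are instrumentation, hardware-dependent by nature. A
buffer-of-buffers variant (queueing copies so nothing is missed) is
deliberately not implemented: it either accumulates unbounded backlog or
degenerates into reading the live buffer, and the missed-sample counts are
the honest currency here.

Reports mirror the streaming results format: a CSV with one row per
classification (`id`, `location` as a `start-end` span $n$ samples wide in
stream coordinates, `classification`, `confidence` as a percentage) and a
JSON summary with mean per-stage timings, mean missed samples, and both a
plain and a beat-count-weighted mean confidence (the weighting scheme behind
a "weighted confidence" summary is otherwise unspecified, so both are
labelled and reported).

## Synthetic data: what it is and is not

The generator builds beats as sums of Gaussian bumps (P/QRS/T-like
components), places them at RR intervals drawn from a normal (mean 0.8 s,
sd 0.05 s, truncated below at 0.6× the mean so beats cannot collide), adds
white noise (sd 0.03 in amplitude units where the QRS peak is ~1.0) and
sinusoidal baseline wander (amplitude 0.05, 0.33 Hz), and annotates each
beat at the argmax of its clean rendered segment. Two channels are emitted
(the second an attenuated copy with independent noise) at 360 Hz. The two
presets — a narrow tall "N" and a wide, P-wave-free "V" — are chosen to be
separable far above the noise floor (rendered-shape correlation < 0.9,
amplitude contrast ≫ 5× noise sd).

These defaults are the package's study conditions: chosen once to emulate a
clean two-class excerpt of an ambulatory recording at desk scale, not tuned
to any test outcome. What passing tests show: the full pipeline — I/O,
windowing, encoding, training, evaluation, streaming — is internally
correct, deterministic under seeds, and can learn cleanly separable
morphologies to ≥ 0.95 held-out accuracy within 10 epochs. What they do not
show: performance on real ECG, where classes overlap, morphology drifts,
electrodes move, and the class distribution is heavily skewed. The
published-scale accuracies on the 48-record reference database require that
database; the pipeline supports it directly (WFDB-dialect reader, the same
`build_dataset()`/`train_cnn()`/`evaluate_model()` path), but no accuracy
claim is made for data the package does not ship.

## Problem sizes and numerical choices

The test suite trains the full 180×64 network on ~270 images from a
4-minute synthetic record (batch 64, 10 epochs, a few tens of seconds) and
uses an 8×6-input miniature of the same layer stack for gradient checks and
training-mechanics tests; conversion oracles run on 1,000 random
(signal, limits, height) triples; skew uniformity uses 10,000 draws. These
sizes were picked so the whole suite runs in a couple of minutes while still
exercising every code path at full geometry at least once.

Degenerate inputs are handled explicitly: empty annotation lists yield empty
window sets (not errors); a dataset with zero usable windows raises a
distinct error; bad quantization limits (max ≤ min) raise a parameter error
before any work; geometry mismatches between images, buffer and model are
rejected before training or streaming starts; flat windows reject in the
center check as described. Signal amplitudes written to disk are quantized
at a declared gain (default 200 ADC units per mV, 16-bit), bounding
round-trip error at half an ADC step.

## Known limitations

* No denoising or filtering of the raw signal; the encoder quantizes what it
  is given.
* Single-channel analysis; the second channel is carried but not fused.
* No multi-segment or variable-frequency records, and no resampling.
* The training engine is single-threaded CPU code built for desk-scale
  experiments, not a deep-learning framework replacement.
* The synthetic generator models morphology, not rhythm pathology: RR
  intervals are near-regular, so rhythm-defined arrhythmias (e.g. atrial
  fibrillation) are out of its reach by construction.
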