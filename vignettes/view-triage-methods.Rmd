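---
title: "Triage of special mammography views: models, phantoms, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of special mammography views: models, phantoms, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clinical mammography archives mix routine full-field screening views with
special diagnostic acquisitions: spot compression, geometric magnification,
stereotactic biopsy pairs, specimen radiographs, and wire-localization (WL)
images. Special views are taken because something looked suspicious, so
they are strongly enriched for cancers; a model trained on an uncurated
archive learns to recognize collimation circles and guide wires rather
than malignancy. This package implements a triage pipeline that scores
every image with the probability of being a special view and removes
everything above a sensitivity-targeted cutoff, using both DICOM metadata
and pixel content. Headers alone do not suffice: WL images are ordinary
full-field acquisitions with no distinguishing view code, which is why a
dedicated image detector exists for them.

## The three models

**Header model.** Tags are extracted without decoding pixels. The field
schema is fit on the training split only: a field is dropped when more
than 10% of training records miss it, or when its keyword marks it as a
date/time stamp, a device identifier, or a demographic attribute. Two
deliberate exemptions: `ExposureTime` is exposure physics, not a
timestamp, and `PatientOrientation` is geometry, not demographics; both
are informative and retained. Retained numeric fields keep their raw
values with absences replaced by the training median (per position for
multi-valued tags such as `DetectorActiveDimensions`); every retained
field also contributes a 0/1 missing-flag column, and categorical fields
are one-hot encoded against the training vocabulary, with unseen values
mapping to all zeros. A present-but-empty `ViewModifierCodeSequence` is
treated as an observed empty category rather than a missing value — the
sequence is routinely written empty for unmodified views, and treating
emptiness as missingness would eject the single most informative field on
the 10% rule. The classifier is a gradient-boosted tree ensemble
(binary logistic objective, exact split enumeration for determinism) with
a stratified fivefold cross-validated grid over tree depth {2, 3, 4},
learning rate {0.05, 0.1} and rounds {100, 300}, selected on mean
validation auROC with ties broken by grid order. An elastic-net logistic
regression (mixing grid {0, 0.25, 0.5, 0.75, 1}, penalty path searched
internally) and a single-field baseline on `ViewModifierCode`
(Laplace-smoothed category positive rates, α = 1; absent values scored by
the absent group's rate; unseen categories by the global rate) are
provided for comparison.

**General image model.** Images are bilinearly rescaled to 99 × 99 without
preserving aspect ratio and min–max normalized per image (a constant image
maps to zeros; per-image normalization is robust to vendor intensity
scales). The network is a truncated Inception-style topology: a
two-convolution stem with max pooling, four inception blocks (1×1, 1×1→3×3,
1×1→3×3→3×3, and pool→1×1 branches, concatenated), global average pooling,
dropout (rate 0.5), and a single dense sigmoid unit. Which four blocks of
the reference Inception-v3 constitute "the first four" is ambiguous across
its heterogeneous block families; this package commits to a uniform block
family and documents the choice as its own. The grayscale channel is
replicated to three so that externally supplied pretrained weights remain
structurally possible (`init = "pretrained"` is an optional hook; random
initialization is the tested path and the default). All layers train with
Adam (learning rate 1e-3, batch 32) on binary cross-entropy. A
`width_multiplier` scales every filter count by its ceiling so desk-scale
experiments train in minutes; the tested configuration is width 0.25.

**Wire-localization detector.** The full-depth topology (eight blocks,
299 × 299 input) with only the final dense layer trained, at learning rate
1e-2. The frozen trunk is applied once per image; pooled features are
standardized with training statistics and the head is trained with Adam on
a class-weighted cross-entropy (positives weighted by the inverse class
ratio). WL prevalence is of the order of one percent, and an unweighted
head barely leaves its prior at that imbalance. With random initialization
the head is fit on features of a random frozen trunk; this is permitted
(and logged) — on the phantom benchmark those features are already
linearly separable — and full-layer training remains available via
`train_all_layers = TRUE`, though head-only training is the default
because it is the configuration retained by the method this package
implements.

**Test-time augmentation and fusion.** Each image model scores the
original and the horizontally mirrored image; the general model averages
the two scores and the WL detector takes their maximum (maximum favors
recall for a localized feature that mirroring may render easier or harder
to see). Fusion is fixed algebra, not a learned stacker: the combined
image score is `max(s_img, s_wire)`, and the final ensemble is
`max(s_wire, (s_img + s_hdr) / 2)`. Whether the image term inside the mean
should be the general score or the wire-fused score is ambiguous; the
general score is the default and `image_source = "combined"` switches to
the other reading.

**Threshold selection.** Sensitivity is a step function of the threshold
with jumps only at observed scores, so the largest cutoff whose
sensitivity meets the target is found exactly by scanning the observed
scores plus zero, in descending order. Classification uses
`score >= threshold`, which maximizes sensitivity at any given cutoff.
The split on which the threshold is chosen is explicit in the
configuration (validation by default).

## Evaluation statistics

auROC is the Mann–Whitney estimator with ties counting one half. DeLong
confidence intervals and the paired test are computed from per-case
structural components (the same ½-tie convention), with the covariance of
the two models' components entering the variance of the auROC difference;
when two models have no discordance — e.g. both reach auROC 1.0 — that
variance is zero and the test is reported as undefined by an explicit
error rather than a fabricated p-value. The exact McNemar test is the
two-sided binomial tail on discordant pairs, `min(1, 2·P(X ≤ min(b, c)))`
with `X ~ Bin(b + c, ½)` and p = 1 when there are none; the chi-squared
wording used in some reports is treated as an alias for this exact form.
Average precision is the sum of precision times recall increments over
descending unique score thresholds. Bonferroni adjustment multiplies by a
caller-declared comparison count, capped at one, because the appropriate
family size depends on the analysis at hand. The unit tests verify all of
these against independent oracles: brute-force pair counting, a longhand
structural-components implementation, closed-form binomial sums,
`binom.test`, and `pROC`.

## The phantom generator

Phantoms are schematic, not anatomically realistic: the contract is that
each class carries a reliable discriminating cue of the same *kind* as the
real one, not radiological fidelity. Full-field phantoms are a bright
half-elliptical "breast" with smooth texture covering essentially the
whole frame; spot/magnification phantoms show tissue only inside a
collimation circle (at least 30% — in practice all — of border pixels at
background level, versus under 10% for full-field); WL phantoms add a
straight guide-wire segment (default width 1.6 px, length half the image
side, intensity 0.98) whose brightness exceeds the 99th percentile of
surrounding tissue; stereotactic phantoms are paired narrow-field panels
with a vertical offset and a fiducial dot grid; specimen phantoms are a
small tissue blob inside a bright rectangular container frame. Rendering
is deterministic per spec and seed, and `artifacts = FALSE` suppresses all
class cues so that every class renders as a plain breast — the negative
control that shows the generator, not the classifier, carries the signal.

Headers are drawn per class: the view modifier code sequence carries a
spot/magnification code for 90% of spot/magnification views with a 5%
leakage rate onto full-field views (the header model should be good but
imperfect, leaving headroom for the image models); WL views never carry
one. Magnification factor is present for ~97% of images, near 1.0 except
for the magnification subset of spot views (1.3–1.8) — an early draft gave
this field 50% missingness, which silently excluded it on the 10% rule and
contradicted the field hierarchy the generator is meant to emulate, so
presence was raised to realistic levels. Compressed-breast thickness,
kVp, grid state, and exposure time shift moderately by class;
`RelativeXRayExposure` is deliberately only weakly class-dependent so that
the modifier code remains the leading signal. `CompressionForce` has 25%
missingness and exists to exercise the high-missingness exclusion path.
Decoy date/time, device-identifier, and demographic tags are always
emitted so schema fitting has something to reject. A
`confound_manufacturer` option skews special views toward
outside-institution vendors to emulate referral bias; it is off by
default. Files are written as DICOM Part 10 (explicit VR little endian)
through the package's own codec, which also reads implicit VR and
defined/undefined-length sequences; written files round-trip byte-exactly
and are cross-checked against pydicom in the test suite where available.

The default labeled composition is 4000 images — 3406 full-field, 555
spot/magnification, 24 stereotactic, 6 wire-localization, 9 specimen —
split 4:1:1 into train/validation/holdout with an allocation that is
simultaneously stratified per class (largest remainder) and exact on the
global split totals. A WL-augmentation step emulates report-keyword mining
by adding synthetic WL cases until a requested total (57 at full scale) is
reached, distributed proportionally across splits. One RNG stream drives
split assignment and another the per-image content, both derived from the
corpus seed by fixed offsets, so regenerating pixels never perturbs
splits.

## The seeded benchmark

The tested end-to-end configuration (seed 0) uses a 1200-image corpus with
the same class proportions as the full composition, augmented to 17 WL
cases — the 57-case fixture scaled by 1200/4000, preserving WL prevalence
(~1.4% of images, well under the 5% ceiling the WL detector is specified
against) — at phantom size 128 px, width multiplier 0.25, and 10 training
epochs for both image models. These sizes are the package's choice of a
desk-scale experiment: large enough that the header model sees a stable
field hierarchy and the WL detector has double-digit training positives,
small enough to train in about two minutes per model on one CPU. On this
benchmark the validation ensemble auROC exceeds 0.98, the header model
exceeds 0.90 with a `ViewModifierCode`-derived column as its top feature,
the WL detector's validation recall at threshold 0.5 is at least 0.90, and
fusion never trails any component by more than 0.01 — all recomputed by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R` at run time.

What passing these tests shows — and does not. The phantom classes are
visually separable by construction, header noise is stochastic but
well-behaved, and there is no vendor heterogeneity, burned-in annotation,
or label noise. Success here demonstrates that the pipeline's mechanics
(feature engineering, training, fusion, thresholding, evaluation) are
correct and that the models can extract the signals the generator plants;
it does not certify performance on clinical data, where the signal is
weaker and confounded (the manufacturer field in particular can encode
referral patterns rather than view physics).

## Numerical and engineering notes

The convolution and pooling kernels live in C++ (Rcpp/RcppArmadillo,
im2col + BLAS matrix products; the backward pass rebuilds patch matrices
rather than caching them, trading compute for memory), while topology,
Adam, and the training loops are R. Training is deterministic given seeds
and a fixed thread count (single-threaded tree construction with exact
splits for the boosted model; one worker everywhere else). Scoring streams
files from disk in chunks, so no full-resolution tensor set is held in
memory; per-file read failures are quarantined and reported, never fatal
mid-run. Degenerate inputs have defined behaviour throughout: constant
images normalize to zeros, single-class label vectors and fold counts
exceeding the minority class are errors naming the constraint, absent
fused scores name the offending image, and precision with no predicted
positives is reported as absent rather than zero.

## Known limitations

The codec covers the transfer syntaxes and tags this pipeline needs, not
compressed or big-endian DICOM. The truncated topology is a faithful
*kind* of network, not a weight-compatible Inception-v3. The WL detector's
random-trunk/head-only default is a testing configuration; with clinical
data one would initialize the trunk from pretrained weights through the
provided hook. Saliency visualization and report-text mining are out of
scope; the mined-WL workflow is emulated by the augmentation fixture's
composition.
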