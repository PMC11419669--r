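---
title: "Detecting and analysing epithelial cell divisions with mitoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and analysing epithelial cell divisions with mitoscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cell divisions in a developing epithelium are rare, fast events embedded
in a dense field of near-identical nuclei. In two-channel confocal
time-lapse data (junction reporter + nuclear reporter, one frame every
2 minutes), a division shows a stereotyped motion signature: one or two
frames of a condensed, bright metaphase nucleus, then two chromosome
masses separating over roughly 6 minutes. Wounded tissue adds motile
immune cells and bright nuclear debris that imitate this signature, and
live imaging adds photobleaching and sample drift. `mitoscope` detects
divisions in such movies, extracts their orientations, and computes the
spatio-temporal statistics that characterise how divisions organise
around development and wound healing.

## Pipeline overview

1. (3D data only) project each z-stack to 2D by per-pixel
   sharpest-slice selection (`focus_project()`).
2. Slide a 5-frame window along the movie and encode each window as a
   10-channel image: the nuclear channel at the five frames, then the
   junction channel (`extract_clips()`, `encode_input()`). A 3-frame
   nuclear-only RGB encoding is also supported; it is measurably worse
   at rejecting false positives, which is the reason the 10-channel
   variant is the default.
3. A residual encoder–decoder network maps each window to a probability
   map that marks each division with a filled circle at its
   division-time frame, defined as the last metaphase frame
   (`build_model()`, `predict_movie()`).
4. Circles are called as events by a Laplacian-of-Gaussian blob detector
   and deduplicated across frames by brightest-wins suppression
   (`detect_divisions()`).
5. A second network of the same architecture maps a 120×120 crop around
   each event to an oriented oval; the nematic q-tensor of that oval
   gives the division axis (`estimate_orientation()`).
6. Downstream statistics: wound-referenced banded densities, daughter
   shuffling, and space–time correlation functions.

## The synthetic-data generator

Real training corpora for this task are hand-labelled; to make every
stage trainable and testable at desk scale the package ships a simulator
whose defaults emulate the imaging regime the pipeline targets:
512 × 512 px covering 123.26 × 123.26 µm, 93 frames at 2 min, nuclei of
σ ≈ 1.1 µm on cells spaced ~4.5 µm, two condensed metaphase frames, an
anaphase separation reaching ~6 µm over 6 min, wounds of 8–20 µm radius
closing linearly within 20–90 min, photobleaching of ~0.5 % per frame,
Gaussian-walk drift, and Gaussian read noise plus scaled-Poisson shot
noise (the standard confocal approximation).

The division schedule is an inhomogeneous Poisson process whose
intensity is a linear-in-time baseline — divisions per (100 µm)² per
10 min, declining linearly through the movie, as in unwounded developing
tissue — multiplied by a wound modulation: a suppression disc
(multiplier 0 by default) within 20 µm of the wound edge before 70 min,
and a ring-shaped burst between 20 and 70 µm from the edge whose
amplitude doubles the baseline at its Gaussian peak at 100 min
(σ = 10 min). The unwounded baseline intercept defaults to
9 (100 µm)⁻² (10 min)⁻¹, chosen so that a full-field 3-hour movie
carries on the order of two hundred divisions — the division density at
which labelled corpora of this tissue are assembled; the per-minute
decline (−0.015) brings the end-of-movie rate to roughly 70 % of the
start, the gentle developmental slow-down seen in unwounded pupal
epithelium.

Cell geometry is a Lloyd-relaxed Voronoi tessellation of a jittered
hexagonal lattice with 2-px junction lines; daughters acquire a new
shared edge one frame after division. False-positive bait follows the
stated sources: debris puncta doing a random walk with per-frame
flicker, and immune-cell blobs doing persistent random walks of
1–3 px/frame with transient brightening. Ground truth (divisions with
axes, wound/tissue masks, per-frame cell labels, drift) is recorded
before noise.

What the generator does **not** emulate: mechanically realistic cell
shapes and force balance (no vertex model), intensity heterogeneity of
real reporters, segmentation-grade junction texture, out-of-plane tissue
curvature, and genuinely ambiguous division look-alikes such as
apoptotic extrusions. Passing the synthetic benchmarks therefore
demonstrates that the architecture, losses, calling and statistics are
implemented correctly and have the capacity to learn the division
signature — not that the shipped configuration reaches benchmark-grade
accuracy on real microscopy; for that, the models must be retrained on
labelled real movies with the same machinery.

## The network

The spot-marking formulation turns detection into dense prediction: a
U-shaped network with a residual-block encoder and a skip-connected
decoder, the family used when converting residual image classifiers into
segmentation models. The implementation is configurable in input
channels (3, 10, or anything else), base width and depth. The desk
default — width 16, depth 3, one residual block per level, ~168k
parameters — replaces the classifier-scale backbone (~41M parameters)
because it trains on one CPU core in minutes; the architecture family,
not the parameter count, is what the pipeline depends on. No pretrained
weights are used: training starts from He-initialised weights under a
fixed seed.

The loss is an equal-weight sum of binary cross-entropy and soft Dice:
cross-entropy stabilises early training, soft Dice counters the extreme
foreground/background imbalance of spot masks. Optimisation is Adam
(learning rate 1e-3, batch 4). Both passes run in single-precision
im2col + GEMM C++ kernels; the float32 accumulation error is orders of
magnitude below the training noise floor (the backward pass verifies
against finite differences at ~1e-4 relative error).

Augmentation applies quarter-turn rotations and flips — the exact
subgroup of the usual rotate/flip transforms, chosen because they are
lossless on the pixel grid and commute exactly with mask construction —
to input and target, and Gaussian blur, brightness/contrast and sharpen
to the input only.

## Division calling

The response maps are searched with a scale-normalised
Laplacian-of-Gaussian at σ = r/√2 matched to the 10-px training circle;
peaks above a threshold become candidates with sub-pixel positions from
a quadratic fit. Because a model often also fires (more weakly) one
frame before or after a division, candidates within one circle radius
and at most one frame of each other are grouped by transitive closure
and each group keeps only its brightest member. The detection threshold
is not hand-set: it is calibrated once per trained model by sweeping
0.05–0.6 on validation movies and keeping the Dice-maximising value
(`calibrate_threshold()`), and is stored with the model's results.

Matched-event evaluation pairs predictions and truths one-to-one,
admitting pairs within 10 px and ±1 frame — a detection one frame off
is still correct. Pure distance-greedy pairing is suboptimal in
cardinality when admissible pairs overlap densely, so the matcher runs
augmenting-path maximum matching seeded in ascending-distance order:
the matching size always equals the exhaustive optimum (a test
enumerates all matchings on small instances to confirm this) while
nearer pairs are still preferred among equally large matchings.

## Orientation and the q-tensor

The orientation model outputs an oval (semi-axes 50 and 15 px in a
120 × 120 crop) aligned with the division. Its axis is extracted by the
second-moment nematic tensor computed over the thresholded shape region
with centroid-relative coordinates, normalised by the squared region
area; θ = ½·atan2(q_xy, q_xx). Taking the integral over the whole image
with absolute coordinates would carry no orientation information, so the
region/centroid form is used; the normalisation does not affect θ. The
closed form for an ellipse with semi-axes a, b gives
q_xx = (a² − b²)/(8πab) at θ = 0 (≈ 0.1207 for 50/15), which the
rasterised computation reproduces within 2 %; the θ round-trip over 18
angles is accurate to 1°. The threshold defaults to half the image
maximum with q0 ≥ 1e-4 as the degeneracy guard; an intensity-weighted
mode is available and agrees on clean ovals.

## Wound-referenced statistics

The wound is tracked as the centroid of its mask while open; from the
last open frame onward (and for unwounded movies, from the image centre
as a "virtual wound") the wound-site point is advected by the mean local
tissue displacement, estimated by integer-shift cross-correlation of the
nuclear channel within 30 µm — the advection window is a package choice,
as "around the wound site" fixes no number. Distances are exact
Euclidean distance transforms from the wound edge (in µm on the
calibrated grid) before closure and radial distances from the tracked
point after.

Banded densities count divisions per 10-µm annulus and 10-min bin,
divided by the *observed* tissue area of the band (excluding wound and
out-of-field pixels) averaged over the frames of the bin — averaging
rather than summing makes the quantity an area-normalised density per
bin; either convention is self-consistent, and averaging keeps the units
divisions·µm⁻² per bin. A band with no observed area is flagged `NA`,
never zero. The unwounded baseline is an ordinary least-squares line of
density against time; the change heatmap subtracts its prediction from
each wounded bin.

## Correlation functions

The event table is binarised into a 1 µm × 1 µm × 1-frame matrix
(124 × 124 × 89 = 1,368,464 elements in the default geometry; the
spatial bin count is the ceiling of the µm extent, and 89 of the 93
frames are usable because window label frames span frames 2–90). For an
element i, M_i(t, r) is the division count in the annular tube with
radii (r − 10, r] µm and the backward time slab covering lags
[t − 10, t) min, divided by the tube's *observed* volume only — shells
clipped by the field boundary are denominator-corrected, which a
triple-loop oracle verifies exactly. The correlation subtracts the
product of means from the division-conditioned mean; the global mean
⟨M(t,r)⟩ is estimated over a uniform random subset of 1000 elements
(full enumeration when the subset covers the matrix), with the subset
seed recorded in the result. The temporal window is printed backward in
the defining formula and is implemented that way; since the
division-conditioned average runs over all division elements, pairs are
counted once with the later division as the reference, and the
published-style heatmap axis (non-negative lag) is unaffected.

Orientation correlation is the mean nematic dot product
cos 2(θᵢ − θⱼ) over unordered pairs binned the same way: +1 aligned, −1
perpendicular, 0 at 45°. It is invariant under a global rotation of all
axes, and a uniform-θ null scatters around 0 at the 1/√(pairs) scale.

## Desk-scale benchmarks and problem sizes

The reference experiments train on a corpus of 40 simulated movies of
128 × 128 px (30.8 µm) and 26 frames, alternating unwounded and wounded
(6-µm wound with debris and immune bait), split 30/5/5 into
train/validation/test. The detector trains for 12 epochs on up to three
division windows plus one empty window per movie; the orientation model
(width 12 — the oval task is easier and a slimmer model trains faster at
no accuracy cost) trains for 6 epochs on two crops per movie. On one CPU
core the two benchmarks take roughly 10 and 3 minutes. Held-out
performance is summarised as event-matching Dice (detector) and the
median nematic error against the programmed axes (orientation).
Divisions in the first and last few frames have no valid clip window
and are excluded from the evaluation, mirroring the incomplete
information at the movie ends. The burst/suppression recovery and
correlation checks run on schedules sampled at the full 512-px
geometry, pooling 9 wounded and 14 unwounded movies (a few thousand
divisions, the scale of a labelled multi-movie corpus); since a single
band-by-time bin holds only a handful of events, the burst time is
located on the area-weighted density change pooled over bands and the
ring location as the 20–70 µm excess over the remaining bands. With
10-min bins, a Gaussian burst centred exactly on a bin edge (100 min)
splits its mass between the two adjacent bins, so recovery is asserted
to one bin's resolution.

## Numerical choices and degenerate inputs

* Movies live in [0, 1]; per-channel min–max rescaling makes the two
  reporters commensurate in the encodings.
* Inputs whose sides are not divisible by 2^(depth−1) are zero-padded
  internally and the output cropped back.
* LoG local maxima are strict on an 8-neighbourhood; plateau ties keep
  the first index. Sub-pixel offsets are clamped to ±0.5 px.
* `q_tensor()` errors on an empty region ("no shape detected") and
  `theta_from_q()` on isotropic shapes (q0 ≤ 1e-4).
* Watershed seeds are connected components within h (default 0.2) of
  the boundary-map minimum with a 5-px minimum seed size; a map with no
  basin yields one region; the one-pixel line between touching cells is
  assigned to neither.
* Track filtering discards tracks with a frame-to-frame relative area
  change above 0.3 or a shape-anisotropy (q0) jump above 0.03 — the
  "large and/or sudden change" rule needs concrete bounds and these are
  configurable.
* Divisions at the first and last two frames of a movie have no valid
  window and are unlabelled by construction.
* All randomness flows through explicit integer seeds; identical
  (configuration, seed) pairs reproduce movies bit for bit.

## Known limitations

* The boundary model is exercised through the three-plane encoding,
  `boundary_target()` and the watershed/tracking stack, but no
  full-scale boundary network is trained in the benchmarks: at desk
  scale the ground-truth junction render already saturates the
  segmentation metrics, so training one would demonstrate nothing.
* The stack-focuser is functionally equivalent to the common sharpest-
  slice tools (local-variance sharpness, median-smoothed index map),
  not bit-identical to any particular plugin.
* Synthetic-to-real transfer is out of scope: the shipped desk models
  are benchmarks of the machinery, not reusable weights.
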