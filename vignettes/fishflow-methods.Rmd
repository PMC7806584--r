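---
title: "FishFlow: methods and design notes"
author: "FishFlow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FishFlow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Behavioral assays of visual sensitivity in fish record a single animal
swimming in a circular container, typically under infrared illumination in
near darkness, before and after an olfactory stimulus. The readout is a
binary judgement per short clip: did the animal show a behavioral change —
most prominently the escape response, an abrupt turn followed by rapid
swimming in the opposite direction — or not. Scoring such clips by eye is
slow and requires trained observers. FishFlow automates the judgement with
a five-stage pipeline: per-frame fish detection, circular masking, dense
optical flow between consecutive masked frames, fusion of the flow
visualizations into one *trajectory image* per clip, compression of that
image to a low-dimensional feature vector, and binary classification,
optionally after generative data augmentation.

The package also ships a synthetic scene generator that emulates the assay
closely enough to exercise and validate every stage without laboratory
footage; all tests and the bundled acceptance analysis run purely on
generated data.

## Synthetic scenes

`sceneConfig()` describes a clip: a dark arena disk (radius 112 px in a
256x256 frame by default) with a central post, and one bright ellipse
(semi-axes 9 x 4.5 px) orbiting near the wall at constant angular speed
(default 1.2 rad/s), oriented along its direction of motion. An escape
event at `eventTime` reverses the sign of the angular velocity and scales
its magnitude by `speedMultiplier` (default 2): the published descriptions
of the response give its character — turn, then swim away rapidly — but
not its magnitude, so both are configurable and the defaults are stated
choices, not measured facts. Nuisance factors mirror what degrades real
recordings: a global light level, Gaussian sensor noise (`noiseSigma`, in
8-bit gray levels; default 3), and with probability `reflectionProb` per
frame a dimmer mirrored ellipse just outside the arena wall, emulating
surface reflections that a detector may report as a second fish.

Clip rendering is a deterministic function of the configuration including
its seed. A four-second clip at 25 fps — the default, matching the
clip length used in behavioral scoring — is 100 frames; `makeDataset()`
derives per-clip configurations (varying speed, phase, direction, light
and event time) from a master seed and returns them *lazily*: a rendered
160-clip corpus at full geometry would occupy ~8 GB, so clips are
materialized one at a time and discarded once reduced to a trajectory
image.

What the generator does **not** model: fish body articulation and texture,
the visible rotating stimulus drum, radial excursions of the swim path,
occlusion by the post, multi-fish scenes, and compression artifacts. A
passing test suite therefore demonstrates the pipeline's mechanics and its
statistical protocols on idealized motion, not performance on laboratory
footage.

## Detection and masking

The detector contract is pluggable (`detectorConfig(backend = ...)`); the
reference backend is classical: a per-pixel temporal median over up to 49
evenly spaced frames gives a background model, and each frame's absolute
difference against it is thresholded (default 0.08 on [0, 1] intensities —
about half the fish-to-background contrast at the dimmest light level the
dataset generator emits). Connected components of at least `minArea` = 12
px become detections; each component's axis-aligned box is reported with a
deterministic surrogate confidence, its area normalized by the largest
component's area. Boxes are half-open in 0-based pixel coordinates, so
area is `(x_max - x_min) * (y_max - y_min)`; pixel centers sit at integer
coordinates.

The box centroid, rounded half-up to the nearest pixel, is taken as the
fish location and dilated to a disk of radius 10 px — the mask passed to
the flow stage. Frames without a detection contribute an empty mask and
hence a black flow frame; this is deliberate tolerance, since sporadic
misses are noise the downstream stages must absorb.

Detector evaluation follows the PASCAL VOC regime: detections ranked by
confidence, greedy matching against at most one ground-truth box per
frame, a match requiring IoU at or above the threshold, and average
precision computed as the area under the all-point interpolated
precision-recall curve (VOC-2010 style; the 11-point variant is available
behind a flag). With a single class, mAP equals AP. The implementation is
tested against an exhaustive enumeration oracle on all small instances
and a pixel-set IoU oracle.

## Tracking: dense flow and trajectory images

Dense optical flow uses the polynomial-expansion method: each frame is
locally approximated by quadratic polynomials under a Gaussian
applicability (window half-size 5, sigma 1.1), and displacements are
estimated from how the expansion coefficients transform, with the local
linear systems averaged over a 15-px box window, three refinement
iterations per level, and a three-level image pyramid (scale 0.5). The
kernel is implemented in C++ in this package because no installed R
library provides dense optical flow. Two numerical guards matter: a local
system is solved only where it is well conditioned (determinant above
1e-12 and trace above 1e-6 — flat, textureless neighborhoods carry no
displacement evidence and solve to zero), and displacements are clamped at
one window size.

Masked flow is computed *on masked frames* (background zeroed), and the
returned field's support is restricted to the union of the two frames'
masks. The restriction is part of the field's contract — displacement is
only meaningful where fish pixels exist — and it is what makes the masking
property hold in the estimator: without it, the box-averaging spreads
responses beyond the disk and the mask edge itself (which moves with the
fish) adds energy, so a masked field could carry *more* total energy than
the unmasked one. With the restriction, masked flow energy is bounded by
full-frame energy on every pair we generate.

Each flow field is rendered as a color image by the conventional mapping —
direction to hue, magnitude to value at full saturation, magnitudes
normalized by a cap of 10 px/frame (about the post-event speed at default
geometry) — and the per-pair images are fused into one trajectory image by
a per-pixel, per-channel maximum, then resized bilinearly to 256x256x3.
The published pipeline says only that the flow frames are "combined"; max
was chosen because it preserves faint early motion against later, brighter
motion and is idempotent and permutation-invariant. A sum-then-normalize
fusion is available (`method = "sum"`).

One consequence of channel-wise max fusion is worth stating: when the
reversed pass of an escape clip retraces the original arc, opposed hues
overlay and partially blend/desaturate rather than both surviving in pure
form. Escape clips still leave a large secondary hue mass outside the
dominant direction's +/- 45 degree window (calibrated on the generator:
roughly 0.15-0.35 for escape clips versus below 0.02 for no-change
clips), and the tests use exactly that statistic.

## Compression: the autoencoder

Trajectory images are compressed by a single-hidden-layer autoencoder,
encoder $y = s(Wx + b)$ and decoder $z = s(W'y + b')$ over the flattened
image $x \in [0,1]^d$, $d = 256 \cdot 256 \cdot 3$, with $s$ sigmoid by
default (ReLU optional; cross-entropy loss always uses a sigmoid output).
The latent width defaults to 64 values — wide enough to reconstruct the
arcs, narrow enough for mixtures and classifiers fitted on 160 items —
with {16, 32, 64, 128} used in the capacity-sweep diagnostics.

Training minimizes mean squared reconstruction error (or mean Bernoulli
cross-entropy) with Adam (learning rate 1e-3, batch 32, 12 epochs by
default) from a *PCA-based initialization*: the encoder starts along the
top latent-dim principal axes of the training images, scaled so sigmoid
pre-activations have roughly unit spread, and the decoder starts with the
matching (moderately scaled) principal axes and its output bias at the
logit of the clamped pixel means. Deliberately, no slope correction is
applied at the output nonlinearity: amplified initial weights saturate
the output sigmoid and stall training. This start sits near a good
solution, so
short trainings converge reliably, and—because principal subspaces are
nested—capacity is strictly nested across latent widths, so mean
reconstruction error decreases with the latent dimension on the fixed
diagnostic batch. (At a finite step budget the widest model can
occasionally trail the 64-wide one by a fraction of a percent on some
corpora — twice the parameters share the same number of optimizer steps —
so the monotonicity diagnostic is defined on its fixed batch, not claimed
for every corpus.) The Adam update is performed in place in C++; at ~25
million
parameters, R-level temporaries would otherwise dominate the runtime.

The autoencoder is trained once on all trajectory images of the corpus:
it is an unsupervised stage that never sees labels, and the published
protocol compresses the full corpus before any classification. (Training
it per cross-validation fold would be the stricter leakage stance; at
these problem sizes it changes nothing downstream but multiplies the cost
tenfold.)

## Augmentation: class-conditional mixtures

For each behavior class, a Gaussian mixture
$p(x) = \sum_{i=1}^{K} \phi_i \, \mathcal{N}(x \mid \mu_i, \sigma_i)$,
$\sum_i \phi_i = 1$, is fitted to the class's feature vectors by EM
(k-means start, log-space responsibilities, convergence at relative
log-likelihood change 1e-8, at most 200 iterations). The component count
is not specified by the published method; the default is K = 2 with
diagonal covariances — with ~80 samples in 64 dimensions, full covariances
are underdetermined — and a ridge of 1e-6 is always added to the diagonal,
with a warning when a component's variance collapses toward zero (which
legitimately happens for saturated latent units). The per-iteration
log-likelihood trace is stored, and EM's monotonicity is asserted in the
tests; fitting is also cross-checked against an independent mixture
implementation.

Sampling draws a component per vector from $\phi$ and then a normal draw;
10,000 vectors per class is the working default. Following the augmented
evaluation protocol, the augmented set consists of the synthetic vectors
only (18,000/2,000 per fold under the 90/10 protocol); appending the real
features is available behind `includeReal = TRUE` but is not the default
protocol.

## Classification and evaluation

Five classifier kinds sit behind one configuration: a soft-margin linear
SVM (cost C, default 1), L2-regularized logistic regression (the ridge
weight is 1/(nC), matching the penalized log-loss formulation with
unpenalized intercept), Gaussian naive Bayes (implemented in-package from
per-class, per-feature sample moments with a 1e-9 variance floor; its
per-feature Gaussian likelihood is exposed as `gaussianLikelihood()`), a
decision tree (Gini, cp = 1e-4, effectively unlimited depth), and a
random forest (100 trees). Features are standardized with training-fold
mean/variance for the margin-based models only. Predictions are hard 0/1
labels; a decision score of exactly zero resolves to 0 — the conservative
"no change" default.

Evaluation is repeated random-subsampling validation: 10 independent
stratified 90/10 splits (144/16 at n = 160; 18,000/2,000 at n = 20,000),
reporting accuracy, precision, recall and F1 as mean and standard
deviation across folds. Disjoint-partition K-fold is deliberately *not*
used: the protocol is defined by its explicit 90/10 split sizes.
Precision and recall are computed for the positive class (1 = behavioral
change), with empty denominators scored 0.

## Problem sizes and determinism

The bundled acceptance analysis and the heavy tests run on a corpus of
160 synthetic four-second clips at 25 fps (80 escape, 80 no-change) with
the generator's default nuisance levels — the corpus size and clip length
mirror the study design the pipeline addresses. On one CPU core the corpus
takes a few minutes to reduce to trajectory images, and autoencoder
trainings take one to three minutes each; these sizes were chosen as
desk-scale defaults.

Every stochastic stage takes an explicit seed, and all stage seeds derive
deterministically from a single master seed; identical configurations give
bit-identical clips, identical trained weights and identical verdicts.
Package functions save and restore the caller's RNG state.

## Known limitations

* Synthetic clips idealize the assay; none of the reported numbers are
  claims about laboratory footage.
* The reference detector assumes a static background and a single bright
  moving object; it is a stand-in behind the same contract a deep
  detector would implement, not a re-implementation of one.
* Channel-wise max fusion partially blends opposed hues when an escape
  retraces its own arc (see above); classification relies on the learned
  features, not on pure hue separation.
* Reading video containers requires prior frame extraction; the package
  ingests directories of numbered PNG frames (no video decoder is among
  the package's dependencies).
* Per-clip verdicts are aggregated to a per-video statement only as an
  "any clip positive" convenience flag, which is an artifact convention,
  not part of the evaluated protocol.
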