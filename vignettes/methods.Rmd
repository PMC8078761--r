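---
title: "Estimating coiled C. elegans postures from video: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating coiled C. elegans postures from video: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemapose)
```

## The problem

The pose of a crawling *C. elegans* worm is its centerline, parameterized
here as a vector of $N = 100$ tangent angles $\theta = (\theta_1, \dots,
\theta_N)$ measured head to tail between $N + 1$ equidistant skeleton
points. Classical trackers recover $\theta$ by image skeletonization, which
fails whenever the body occludes itself — omega turns, delta turns and other
coils. This package estimates $\theta$ from a single grayscale image with a
convolutional network, and removes the need for human labels by training the
network entirely on synthetic images: a generative model of posture supplies
arbitrarily many target centerlines, and a patch-warping renderer bends the
texture of a few classically-tracked ("labeled") frames onto each target.

The pipeline is the one a worm lab would run on tracker output: standardize
frames, fit the posture model, render a training set, train, predict every
frame, then score, filter, orient, interpolate and smooth the resulting
angle series. A behavior module computes the posture-scale roaming/dwelling
analysis (two-state hidden Markov model on windowed centroid kinematics,
body-wave phase dynamics and turning statistics in eigenworm coordinates).

## Posture geometry

Angles and skeletons interconvert by integration,
$S_{i+1} = S_i + dS\,(\cos\theta_i, \sin\theta_i)$, and differentiation
(`angles_to_skeleton()`, `skeleton_to_angles()`); $N$ angles correspond to
$N+1$ points, and skeletons with a different point count are resampled by
arc-length linear interpolation. All angular comparisons go through the
wrapped difference $\epsilon(\alpha,\beta) =
\operatorname{atan2}(\sin(\alpha-\beta), \cos(\alpha-\beta))$; the distance
between two centerlines is the root mean square of $\epsilon$ over the
body, $d(\theta^{(1)}, \theta^{(2)})$.

A centerline and its head–tail flip, $\mathrm{flip}(\theta) + \pi$ (order
reversed, each angle rotated by $\pi$), trace the same curve. Because a
single image often cannot distinguish head from tail, the two are treated
as equivalent labels throughout: the training loss is
$\min\{d(\hat\theta, \theta_a), d(\hat\theta, \mathrm{flip}(\theta_a)+\pi)\}$
(`symmetric_loss()`), and the orientation is resolved only later, in time.

Angle storage convention: image coordinates are $x$ = column, $y$ = row
with $y$ increasing downward; angles are $\operatorname{atan2}(\Delta y,
\Delta x)$. Linear operations on posture (PCA, mixture modeling,
projections) require tangent-angle profiles that are continuous along the
body, not wrapped elementwise into $(-\pi,\pi]$ — a coiled worm's angles
wind through more than $2\pi$. `unwrap_body()` restores continuity (up to
one global $2\pi$ offset, which is why mode *errors* are computed by
projecting the wrapped elementwise error field rather than by differencing
projections).

The eigenworm basis (`compute_eigenbasis()`) is the mean-subtracted PCA of
a shape library; the first two components carry the traveling body wave,
the third ($a_3$) the overall turning amplitude. Bands of $|a_3|$ index
deep turns: roughly $10 \le |a_3| < 20$ for omega-like turns and
$|a_3| \ge 20$ for delta turns.

## Generative shape model

`fit_shape_model()` fits a full-covariance Gaussian mixture to a library of
centered (rotation-free, body-continuous) angle vectors with EM. Defaults
follow the full-scale protocol — 270 components for a library of ~15000
shapes, selected by the Akaike information criterion
(`select_components_aic()`; $\mathrm{AIC} = 2k - 2\log L$ with $k$ the free
parameter count) — and scale down with the library. Numerical choices:
k-means initialization (seed-controlled, deterministic), $10^{-6}$ added to
covariance diagonals every M step (100-dimensional components with few
members are otherwise singular), and convergence when the mean
log-likelihood improves by less than $10^{-3}$. Because abundant uncoiled
postures would otherwise dominate the fit, `subsample_uniform_a3()`
balances a library across the turning-mode range by inverse-frequency
weighting over a 30-bin histogram of $a_3$ (the bin count is a package
choice; the flatness of the result is property-tested).

`sample_shapes()` draws i.i.d. postures; the training-set generator adds a
global orientation uniform on $(0, 2\pi]$ and assigns the head end with
probability $1/2$.

## Synthetic images by reverse skeletonization

`render_synthetic()` bends a labeled reference frame into a target posture:

1. the target skeleton is integrated from the target angles with
   $dS = L_{\mathrm{worm}} / (N_S - 1)$ and centered on the canvas (the
   centering translation is rounded to whole pixels so that rendering a
   reference's own pose is resampling-exact);
2. rectangular patches along the reference skeleton — one per `step`
   indices, `step` $= N_S/16$, width $1.2\times$ the local body width so
   that nearby background travels with the body — are mapped affinely onto
   the corresponding target rectangles; overlaps blend at weight 0.5,
   drawn tail-first so head patches land on top;
3. protrusions are clipped by the expected worm outline (per-segment
   quadrilaterals of the local width plus end caps; the clip uses a 1 px
   padded width so the body's soft brightness edge survives);
4. a 3×3 median filter smooths patch seams, and all non-worm pixels take
   the reference background value.

Widths at every skeleton point come from the three labeled widths (head,
midbody, tail) by piecewise-linear interpolation between landmark fractions
(0.15, 0.5, 0.85) of arc length — the landmark positions are a package
choice, configurable. Augmentations (all seed-driven): translation up to 5%
of the image side, length 90–110%, width multiplier 1.1–1.3, draw-order
flip with probability 0.5, and an extra Gaussian blur 25% of the time with
kernel 3–10% of the side, capped at 13 px.

## Network and training

`build_pose_network()` constructs a compact residual regressor: a 7×7,
stride-2, 32-filter stem with 2×2 max pooling, three stages of
pre-activation basic blocks (filters 32/64/128, three blocks per stage,
leaky rectifier with slope 0.1), global average pooling and a dense layer
of 100 outputs. The full-scale defaults target 128 px inputs, 500k
synthetic training images, 10k labeled evaluation images, batch 128, Adam
at $10^{-3}$, 100 epochs, keeping the checkpoint with the best evaluation
loss. The network emits raw angle values with no output activation — the
loss wraps differences, so branch choice is free — and images are
normalized per frame by subtracting the mean (dominated by the uniform
background). The implementation is compiled (im2col + BLAS), single
precision, fully deterministic given the seed.

Two optimizer conveniences matter for short, CPU-scale trainings and are
off/neutral at full scale: a geometric learning-rate decay across epochs
(`lr_final`) and optional Polyak weight averaging (`ema_decay`). The
root-mean-square loss has constant per-sample gradient norm (the error
direction is normalized), so the attainable precision floor tracks the
final learning rate; decaying the rate lowers that floor.

## Post-prediction

*Image error.* Lacking coiled ground truth on real data, predictions are
scored by rendering them (`image_error()`): the synthetic reconstruction is
cropped to the worm bounding box plus 2 px and slid over the input frame,
computing the normalized correlation coefficient at every placement. The
error is $1 - |c|_{\max} \in [0,1]$; the absolute value makes
reversed-intensity matches count, and the argmax location recovers the
skeleton position. Frames above a threshold (default 0.3, chosen against
the error distribution of labeled frames reconstructed from their own
labels, `choose_threshold()`) are discarded.

*Head–tail assignment.* `build_segments()` makes a greedy pass over the
prediction pairs: within a segment the orientation minimizing the mean
absolute angle distance to the last aligned frame wins; if both
orientations exceed 30°, the scan looks up to 0.2 s ahead (skipped frames
become gaps) before closing the segment and restarting with a random,
seeded orientation; segments shorter than 0.2 s are dropped. Exact ties
keep the incumbent orientation. `orient_segments()` then flips whole
segments to maximize the cosine similarity of head-to-tail vectors against
overlapping labeled frames, and label-less segments inherit the orientation
of their nearest aligned neighbor through the two closest frames;
unresolvable segments are flagged, never guessed silently.

*Interpolation and smoothing.* Gaps of at most 4 frames are filled per
angle index by a cubic spline over neighboring frames; longer gaps stay
open. Smoothing is a Savitzky–Golay filter with third-order polynomials in
nominally 8-frame windows — the filter needs an odd window, so the centered
9-frame window is used (recorded in the configuration). Both steps are
exact on cubic trajectories, which the tests exploit.

## Behavior: roaming and dwelling at posture scale

`centroid_kinematics()` downsamples the centroid track to 3 Hz, takes
finite-difference velocities ($\Delta t = 1/3$ s), speed, and the angular
speed from three subsequent points, then appends non-overlapping 10 s
boxcar means (windowing without overlap is a package choice).
`fit_roam_dwell()` fits a two-state HMM with diagonal-covariance Gaussian
emissions by Baum–Welch and decodes states by Viterbi; the faster state is
canonically labeled roaming. `direction_angle()` computes
$\Delta\psi = \psi - \Psi$ (centroid heading minus mean body angle),
normalized into $[-\pi/2, 3\pi/2)$, forward iff $\Delta\psi < \pi/2$.
`phase_velocity()` defines the body-wave phase $\phi$ as the quadrant-aware
angle of $(a_1, a_2)$ — written as an inverse tangent of the ratio in some
sources, with both sign conventions in circulation; the sign is a
configuration flag (default $\operatorname{atan2}(a_2, a_1)$) and only
relabels forward versus backward waves. $\omega = \dot\phi$ comes from the
derivative of a cubic-spline fit to unwrapped $\phi$.
`count_body_waves()` counts complete body waves conservatively: within
maximal runs of constant $\operatorname{sign}(\omega)$, peaks of
$\cos\phi$ with prominence 1.95 and at least 8 frames separation.
`turn_distribution()` reports per-state densities of $a_3$ and the
omega/delta band fractions.

## Procedural fixtures: what they emulate and what they do not

`fixture_world()` defines a deterministic generative world: a dark worm
(length 80% of the canvas, midbody width ~1/12 of its length) on a light
background, rendered with radial shading, a faint longitudinal texture,
sensor noise ($\sigma = 0.015$) and optical blur ($\sigma = 0.5$ px) at
30 Hz. Posture lives in three orthonormal modes — a sine/cosine pair at
wavelength 0.65 body lengths rotating at 0.5 Hz (the traveling wave) and a
constant-curvature turning mode — plus small low-pass-filtered shape
fluctuations and a slow drift of the global orientation. Scheduled bouts
push the turning mode to $|a_3|$ up to 26 (deep coils). Frames with
$|a_3| < 10$ are marked "labeled", mimicking classical-tracker coverage
that fails on coils. The eigenbasis is computed from crawl-like draws so
the component ordering (wave, wave, turn) matches the canonical one, while
the shape-model corpus draws $a_3$ uniformly over its range, emulating a
curvature-balanced library.

Passing tests on fixtures therefore demonstrate the machinery — geometry,
generative model, renderer, training loop, scoring, orientation, behavior
statistics — under controlled truth. They do not demonstrate robustness to
real-world nuisances the world omits: non-uniform illumination, moving
debris, worm-size drift, egg-laying events, or texture families unlike the
procedural shading.

## Scaled benchmark sizes

The quantitative benchmarks (`mode_error_benchmark()`,
`reconstruction_error_benchmark()`, `orientation_accuracy_benchmark()`) are
the package's chosen desk-scale protocol: 48 px images, a 5000-shape corpus
with 24 mixture components, 20k rendered training images, ~10 training
epochs (batch 64, learning rate $3\times10^{-3}$ decaying to
$3\times10^{-4}$), 2k held-out synthetic evaluation images, 200 reference
reconstructions, and a 2000-frame orientation video. These sizes keep a
full run on one CPU core in the tens of minutes. A caveat stated plainly:
the reduced schedule performs ~1.5–3k optimizer steps, orders of magnitude
fewer than a full-scale training, and the network is correspondingly less
converged; the mode-error benchmark reports where this budget lands, and
larger `n_train`/`epochs` reduce the error monotonically in our runs.

## Known limitations

- Single worm, 2D, grayscale; no multi-worm scenes or background modeling.
- The renderer reuses reference texture patches; it cannot invent
  appearance beyond the reference pool (no generative texture model).
- Head identity comes from labeled frames and temporal continuity only;
  there is no appearance-based head detector.
- The posture model is only as broad as its shape library; morphologically
  unusual strains need their own library.
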