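---
title: "Methods: dendrite, spine and puncta analysis in synaptrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dendrite, spine and puncta analysis in synaptrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptrace)
```

synaptrace analyses 2D multi-channel fluorescence time series of neurons:
it traces the medial axis of a dendrite between two user-supplied
endpoints, segments the dendrite and measures its width profile, grows
editable polygonal ROIs around dendritic spines, traces spine necks,
classifies spines by morphology, corrects global and per-spine motion, and
counts fluorescent puncta (e.g. smFISH spots) inside every ROI. This
vignette explains each model, its assumptions, the tunable parameters, and
the choices made where the design was genuinely open.

## The image model

Everything operates on a 4-axis intensity array `I(t, c, x, y)`
(timepoint, channel, row, column), held in an `image_stack`. Coordinates
are 1-based `(row, col)` with pixel centres at integer positions;
conversion to ImageJ's 0-based x/y convention happens only when `.roi`
files are written or read. TIFF page layouts are ambiguous, so
`read_stack()` requires an explicit `axis_order` rather than guessing.

## Medial-axis tracing

The dendrite path is formulated as a shortest-path problem. The image is
median-filtered (window `filter_size`) and thresholded (default: the mean
of the filtered image) into an admissible region. A path computed on that
binary region alone would hug the dendrite boundary on curves, so the
region is augmented with the Euclidean distance `d` of each pixel to the
nearest inadmissible pixel (image borders count as walls) and each pixel
is assigned the traversal cost

$$\mathrm{step\_cost}(p) = \frac{1}{1 + d(p)},$$

which is positive (a Dijkstra requirement), bounded, parameter-free, and
strictly decreasing in clearance, so the optimal path runs along the ridge
of maximal clearance — the medial axis. Edges connect 8-neighbours; an
edge costs the mean of its endpoint step costs, times $\sqrt 2$ for
diagonal moves to avoid staircase bias. Endpoints that miss the admissible
region are snapped to the nearest admissible pixel within 10 px
(deterministic lexicographic tie-break); farther than that is an error.

When either image dimension exceeds 512 px the mask is block-mean pooled
by the smallest integer factor `k` that brings it within 512 (a block is
foreground at occupancy >= 0.5), a coarse path is found, and the
full-resolution search is re-run inside a corridor of half-width `2k`
around the upscaled coarse path. The result therefore always lies on
full-resolution admissible pixels, and on the 600x600 validation tube it
is identical to the path computed without downsampling.

The full-rank pixel chain is compressed to editable control points with
Douglas-Peucker simplification (default tolerance 2 px) — a concrete
realization of sampling the path at its major turning points — and
`interpolate_path()` recovers an 8-connected chain by Bresenham
rasterization. The compress/interpolate round trip is property-tested to
stay within tolerance, and path costs are tested for exact agreement with
an independent brute-force Dijkstra on hundreds of random masks.

## Dendritic width and segmentation

Boundaries come from Canny edge detection (Gaussian smoothing at
`gaussian_sigma`, Sobel gradients, non-maximum suppression, hysteresis at
10%/20% of the maximum gradient). Canny runs on the *median-filtered
intensities*, with the threshold entering as a restriction of the edge map
to the neighbourhood of the thresholded foreground. Binarizing first and
edge-detecting the mask would place the boundary systematically outside
the true intensity step, because a median filter evaluated just outside a
bright plateau returns an upper order statistic of the background noise
and so dilates the foreground by a pixel or two per side; the
filtered-intensity formulation keeps the edge on the step itself.

At every path pixel an ellipse is oriented with a small preset semi-minor
axis (2 px) along the path and its semi-major axis normal to it. The
semi-major length grows 1 px at a time, independently per side, until the
ellipse arc — sampled at <= 1 px spacing over +/-45 degrees about the
normal — touches an edge pixel. The arc test is the point of the ellipse
construction: a single outward ray escapes through any 1 px gap in the
edge map, while the arc is guaranteed to intersect a flanking edge.
Growth is capped at `max_semi_major` (30 px) with the point flagged.

Raw widths are multiplied by `width_multiplier` (slider equivalent,
default 1) and passed through the width-continuity smoothing condition:
a half-width exceeding the running median of its 25-point neighbourhood
by more than `smoothing_strength` (default 0.5, i.e. 50%) times that
median is replaced by the running median, and flagged. Two choices here
are deliberate. First, the window (25 path points, ~2.5 um at 0.1 um/px)
must exceed twice a typical spine footprint (spine head plus neck span
~10-15 path points), otherwise the median itself is dragged up while a
spine passes. Second, flagged points are replaced by the *median*, not by
the tolerance bound: replacement by the bound would leave every spine
crossing recorded at 1.5x the shaft width, defeating the stated purpose of
the condition (keeping protrusions out of the width estimate). With these
choices, adding six spines to a tube changes the mean recovered width by
well under 1 px. `smoothing_strength = Inf` disables the condition.

The segmentation mask is the union of the per-point ellipses; per-(t, c)
statistics record luminosity along the axis, width in physical units, and
total mask luminosity. Accuracy is evaluated pixel-wise by recall,
precision and their harmonic mean F1 (empty-mask conventions: a metric is
0 when its denominator is 0 and the other mask is non-empty; two empty
masks score 1). A naive baseline — a straight chord of 2 um thickness
drawn between the endpoints — is provided for context and scores far below
the model on curved dendrites (F1 0.14 vs 0.92 on the curved-tube scene).

## Spine ROIs

From each spine centre `s0`, eight rays step outward along the cardinal
and ordinal unit directions, `s_{i,d} = s0 + i v_d` rounded to the pixel
grid. Each ray carries an independent counter `c_d` incremented once per
violated rule per step:

* **luminosity drop-off** — intensity below `drop_factor` (default 0.4)
  times the seed intensity `l0`;
* **other-spine** — the point is closer to another centre than to its own;
* **dendrite** — the point lies on the dendrite segmentation mask;
* **fall-back** — the step index exceeds `max_extent` (30 px).

A ray halts when `c_d >= n_break`; its vertex is the last point before the
halting step, and the eight vertices form the octagonal head ROI. Rays
step on a median-filtered copy of the frame (window `filter_size = 3` in
the rule parameters), so single noisy pixels cannot halt a ray; this is
what keeps ROI quality usable down to SNR ~1. The default `n_break = 3`
places vertices slightly outside the intensity structure so the octagon
*encompasses* the head; a smaller counter halts rays on the last bright
pixel, inscribing the octagon inside the head disc and systematically
under-covering it. At the default, head-ROI recall and precision both
stay above 0.7 on disc ground truth at SNR >= 3. The final polygon averages, vertex
by vertex with per-direction correspondence, the octagons grown from the
seed and from its four one-pixel cardinal perturbations (five polygons;
out-of-bounds seeds are skipped), which decouples the result from the
exact click position. All polygons are editable: vertices can be moved,
inserted or deleted with invariants re-checked.

A local-background ROI is a translated copy of the head ROI placed by a
deterministic outward spiral search (from 1.5x the head circumradius, 2 px
steps, 16 angles per ring, 50 px cap) at the first collision-free
position.

## Spine necks and classification

The neck reuses the medial-axis machinery on a small window: start at the
spine centre, end at the nearest dendrite-mask pixel, binarize the crop,
build the cost field, trace the shortest path, segment it with the width
machinery (semi-minor 1 px, necks are thin), and remove any overlap with
the head ROI. Failure — no admissible path (unilluminated neck) or a path
shorter than 5 px (spine flush with the shaft) — is an explicit absence
marker, never an error, and flows into classification as NW = 0.

Classification uses neck width NW and head width HW: NW = 0 is *stubby*;
NW/HW < 0.5 is *mushroom*; 0.5 <= NW/HW <= 1.1 is *thin* (the boundary
values read inclusively); NW/HW > 1.1 is an *outlier*. The estimators
behind NW and HW are chosen for robustness: HW is the median of the four
opposite-ray spans of the octagon, because the one ray that runs down the
bright neck toward the dendrite would dominate a maximal caliper and push
thin spines into the mushroom class; NW is the lower quartile of the width
profile along the neck path, robust to the flare where the neck meets the
head and the shaft. One known limitation follows from the geometry: a
spine whose neck is genuinely wider than its head (the only configuration
with NW/HW > 1.1) cannot be recovered as an outlier from ROI-based
measurements, since the head ROI necessarily wraps the wider neck; the
class boundary itself is exact and unit-tested.

In **luminosity mode** one head ROI is grown on the per-pixel temporal
maximum projection, covering the spine's maximal extent so intensity
dynamics are measured inside a fixed region; in **area mode** an ROI is
grown independently at every timepoint so the ROI area itself tracks
growth and shrinkage.

## Motion correction

Translations are estimated by phase cross-correlation: the normalized
cross-power spectrum of two frames is a pure phase ramp whose inverse
transform peaks at the shift. Frequency bins with numerically vanishing
energy are zeroed rather than normalized (they carry no phase
information, only noise). Subpixel refinement evaluates the inverse DFT on
a grid of spacing `1/upsample` around the integer peak via matrix-multiply
DFT. Integer shifts in [-10, 10]^2 are recovered exactly on SNR 2 frames;
0.5 px shifts are recovered within 0.1 px at `upsample = 10`.

Global correction estimates each frame against a reference timepoint
(default the first) on one structural channel and translates all channels
by the negated shift, rounding to integers by default (no resampling);
exposed regions are zero-filled and tracked in a validity mask. Local
(per-spine) correction estimates the shift of a small window (twice the
head width on a side) around each spine and then translates *only the
ROI*, never pixels — spine motility remains visible in the data and is
quantified by the recorded local shifts. Externally supplied compensatory
offsets (CSV, one row per timepoint) add to the applied ROI displacement.

## Puncta detection

Spots are detected by scale-normalized Laplacian-of-Gaussian filtering:
responses $2\sigma^2 |\nabla^2 (G_\sigma * I)|$ over a log-spaced grid of
scales in `[min_sigma, max_sigma]`, with maxima taken over the 26-connected
(row, col, scale) neighbourhood. The $2\sigma^2$ normalization puts the
matched-blob response on the intensity scale — a Gaussian blob of
amplitude A peaks at response A — so the per-ROI adaptive threshold

$$t_R(t, c) = \max(R(t, c, j, k)) \times \gamma / 100$$

is directly comparable: at $\gamma = 50$ genuine blobs clear the threshold
comfortably, and at $\gamma = 100$ no scale-space maximum can exceed it.
Two slider-equivalent percentages (`gamma_dendrite`, `gamma_synapse`) set
$\gamma$ independently for the two ROI kinds. One guard scale is appended
on each side of the band and only interior-scale maxima are reported, so
blobs larger than `max_sigma` are rejected rather than appearing at the
boundary scale. ROIs whose maximum intensity does not exceed the
`noise_floor` are skipped outright. Detections closer than the larger of
their two sigmas keep only the stronger response.

For polygon ROIs, candidates outside the polygon are discarded (even-odd
rule, border centres count as inside). For dendrites, the band is tiled
into consecutive quadrilaterals, one per control-point segment, with
normals averaged at interior control points so adjacent quads share their
cross-section edge exactly; the threshold derives from the whole dendrite
ROI, detection runs per rectangle, duplicates across shared edges are
removed, and each punctum is annotated with its arclength along the axis.
`localization_fractions()` tallies puncta per (channel, compartment),
e.g. soma versus neurites.

## The synthetic generator and what it does (not) show

`render_fixture()` draws tube-like dendrites of known centreline and
width, disc spine heads with rectangular necks, and Gaussian puncta as
intensity *plateaus* plus Gaussian blobs, then applies per-frame rigid
drift and per-spine wander, then additive Gaussian noise and optional
salt-and-pepper noise, rounding to non-negative integers. Plateau
rendering keeps ground-truth masks unambiguous. The reported SNR is
(structure mean − background mean)/noise SD, measured before the
clamp at zero (clamping would otherwise inflate the background mean at low
SNR). Identical spec and seed give bit-identical stacks.

Defaults model a typical confocal setup: 0.1 um/px, a 10 px (1 um)
dendrite, plateau intensities 300 over background 20, structural SNR 5;
puncta use amplitude 400, sigma 2.5 px and amplitude/10 noise, a typical
smFISH contrast. The gallery (`fixture_gallery()`) fixes the validation
scenes: straight and curved tubes, a tube with six spines spanning the
four morphological classes, a crowded pair 6 px apart, a puncta field with
soma and dendrite compartments, a drifting 5-frame series, and an SNR
ladder at 0.5, 1, 2, 3, 5.

Synthetic plateaus have sharp boundaries, no point-spread function, no
photobleaching and no intensity gradients, so passing tests demonstrate
the correctness and noise-robustness of the algorithms, not performance
against expert annotation of real microscopy; the latter depends on
structures that only real data provide.

Problem sizes used in validation: scenes of roughly 100x200 px, 200
random 20x20 masks for the path-search oracle, the full 21x21 integer
shift grid on 96x96 frames, puncta counts up to 50 blobs on 220x260
frames, and one 600x600 tube for the downsampling check.

## Parameter defaults and the transfer protocol

General-purpose defaults (`analysis_config()`): median filter 5 px, Canny
sigma 2 px, width multiplier 1, smoothing strength 0.5, semi-minor 2 px,
drop factor 0.4, n_break 3, max extent 30 px, gamma 30 for both ROI kinds,
sigma band [1.5, 4] px. These favour sharp localization on clean data. For
very noisy acquisitions the intended workflow is the transfer protocol:
adjust the sliders once on one image of the dataset — for the SNR-ladder
family, median filter 9 and Canny sigma 3 — and apply the saved
configuration to the rest via `transfer_parameters()`. Configurations
round-trip through YAML, and `run_pipeline()` writes the resolved copy
next to its outputs together with a per-stage log, so every run is
reproducible; reruns are byte-identical.
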