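---
title: "Object-gaze distance analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Object-gaze distance analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogdist)
```

## The problem and the metric

Mobile eye trackers record a scene video together with fixation events —
periods during which gaze is held approximately stationary, each reported
as an (x, y) coordinate in scene-camera pixels. Classical analysis maps a
fixation to an area of interest (AOI) only when the gaze coordinate falls
inside the AOI's segmented mask (an *AOI Hit*). In instrumented manual
tasks (the motivating setting is spinal screw placement, with the screw
and the screwdriver as AOIs) this one-to-one mapping discards most
fixations: operators monitor tools peripherally, so the gaze often rests
*near* an object without touching its mask.

The **object-gaze distance (OGD)** replaces the binary Hit with a
continuous quantity: for every fixation and every AOI,

$$
\mathrm{OGD}(f, a) \;=\; \min_{p \,\in\, M_a}
  \lVert g_f - c(p) \rVert_2 ,
$$

the minimal 2D Euclidean pixel distance between the fixation's gaze
coordinate $g_f$ and the centers $c(p)$ of the pixels $p$ of the AOI's
binary mask $M_a$ in the video frame associated with the fixation. A
fixation whose gaze pixel belongs to the mask scores exactly 0 — the
classical AOI Hit is recovered as the zero of the distance. When an AOI is
not detected at all in the frame, the record takes a **sentinel** value:
the scene frame diagonal, which is also the upper bound of any within-frame
distance (1600 px on the reference 1280 × 960 px camera). Every fixation is
thereby mapped to *every* AOI throughout the trial, yielding one distance
time series per object.

## Camera geometry and visual fields

Pixel distances acquire meaning through the camera's angular scale. The
reference device records 1280 × 960 px over a 60° × 46° field of view at
60 Hz; the horizontal axis defines the scale,
$1280/60 \approx 21.33$ px/°. Visual fields are specified as *diameters* of
visual angle centred on the gaze point — foveal < 2°, parafoveal < 9°,
perifoveal < 18°, near-peripheral < 60° (the device's maximum measurable
angle) — while the OGD is a *radius*, so the conversion halves the diameter:
60° ↦ exactly 640 px on the reference camera. Two threshold sets are
exposed:

* `table_defaults`: the published rounded values 20 / 90 / 180 / 640 px,
  valid only for the reference camera. The rounding of the exact values
  (21.33 / 96 / 192 px) does not follow a single arithmetic rule, so these
  are treated as opaque constants rather than re-derived.
* `derived_from_camera`: the exact unrounded conversion, valid for any
  camera.

Band classification uses half-open intervals $[\ell, h)$ with 0 px (a Hit)
in the foveal band, distances at or beyond the near-peripheral threshold
classified `outside`, and sentinel records classified `undetected`
regardless of stored value.

## Distance computation

Coordinates are 0-based, origin top-left, x rightward, y downward; gaze
coordinates are continuous floats with integer values on pixel centers.
Distances are measured to mask pixel centers, and the Hit test rounds the
gaze to its containing pixel, so "inside the mask" is exactly 0 while the
series remains continuous off the mask. Gaze points outside the frame are
flagged, never clamped, and their distances are capped at the frame
diagonal.

The implementation evaluates the minimum over the mask's 4-connected
*boundary* pixels after the containment test: for a gaze point whose
containing pixel is not in the mask, the nearest mask pixel center is
always a boundary pixel (an interior pixel always has a 4-neighbour
strictly closer to the gaze). This is exact, not an approximation, and is
checked against an independent exhaustive brute-force oracle that shares
no code with it: agreement is exact for integer gaze coordinates and
within $10^{-9}$ px otherwise.

Per fixation, the frame is selected by a **policy**: `midpoint` (default)
takes the single frame at the fixation's temporal midpoint,
`all_frames` takes every frame overlapped by the fixation's half-open time
span. Under `all_frames` the per-frame distances (with undetected frames
sitting at the sentinel cap) are combined by `median` (default), `mean` or
`min`; a record is flagged sentinel only when the AOI is absent in *every*
selected frame. Multiple instances of one AOI label in a frame contribute
their minimum. Frame selection uses the mask stream's frame rate from the
camera configuration; recordings whose masks were subsampled declare the
subsampled rate.

## Derived metrics

The **fixation rate** at a distance threshold $d$ is the fraction of all
fixations assigned to the AOI,

$$\mathrm{FR}(d) = \frac{\#\{f : \mathrm{OGD}(f,a) \le d\}}{\#\{f\}},$$

with inclusive comparison so that $\mathrm{FR}(0)$ equals the AOI-Hit
rate. Sentinel records count in the denominator and satisfy only the cap
threshold, so the sweep of FR over the grid 0 … frame diagonal in 10 px
steps is non-decreasing and ends at exactly 1. When a series carries
multiple trials, the default is to compute per-trial rates and average
them; pooling is available. A duration-weighted variant is provided but
off by default — the definition counts fixations, not dwell time.

Mask quality against manual reference labels uses **intersection over
union**, overlap area divided by union area, with two empty masks scoring
0 by logged convention (the agreement of nothing with nothing earns no
credit).

## Multi-OGD gaze patterns

Joint inspection of two AOIs' OGD series reveals recurring shapes. Four
are operationalised as rule-based detectors on fixation-indexed series;
the qualitative shapes come from observation, while the quantitative
onset/offset rules below are this package's definitions and all thresholds
are parameters (`pattern_params()`):

1. **Glance** — AOI A reaches 0 px for ≥ 1 fixation while AOI B's distance
   increases by more than `tolerance_px` (default 5) over the same
   fixations, and within `return_window` fixations (default 3) A returns
   to within `return_tolerance_px` (default 30) of its pre-Hit value. A
   Hit that never reverts is a sustained fixation, not a glance.
2. **Convergence** — both OGDs decrease together (counter-movement up to
   `tolerance_px` per step) over at least `min_len` fixations (default 2)
   until both lie inside the foveal field, with a Hit on *exactly one*
   AOI at the end; simultaneous Hits on both do not qualify.
3. **Joint excursion** — both OGDs start inside the perifoveal field, rise
   beyond it simultaneously for ≥ 1 fixation, and both return inside it
   before the series ends.
4. **Disappearance** — one AOI's OGD rises to or beyond the
   near-peripheral threshold (which subsumes the sentinel of an
   undetected object) while the other stays inside the perifoveal field
   throughout, with a visible onset fixation before the rise.

Detectors report greedily non-overlapping events per AOI pair; events of
*different* types may overlap and are all reported. `detect_all()` runs
every detector over every AOI pair (direction-sensitive rules in both
directions), deduplicates, and tabulates counts with per-trial mean ± SD.
On noise-free fixtures built by `embed_pattern_series()` each detector
attains precision = recall = 1 for its own pattern with zero cross-type
detections, and detections are invariant to sub-tolerance jitter added to
the non-Hit samples. These fixtures embed each shape with a margin of at
least twice the tolerance from every threshold, padded with flat in-band
values.

## The synthetic scene generator

Because no recordings are distributed, every claim is exercised on
synthetic scenes with closed-form ground truth. A scene specifies a
camera, 1–3 rigid objects (disks or axis-aligned rectangles) with
per-frame trajectories, per-label detection dropout, and a fixation track;
realisation is a pure function of the specification and a seed, with the
random streams for gaze positions, gaze noise and dropout split into fixed
sub-seeds so changing one leaves the others untouched.

Defaults emulate the recording conditions of an instrumented surgical
task: a 1280 × 960 px frame, a disk of radius 40 px (screw-head scale) and
a 220 × 60 px rectangle (screwdriver scale) drifting slowly and never
overlapping (a label image cannot represent overlap), ~26 fixations with
right-skewed durations of mean ≈ 0.65 s over ≈ 22 s, 10 % detection
dropout per label, and a mask stream subsampled to 5 fps — per-frame masks
at full video rate would be needlessly large for a desk-scale test bed,
and subsampled mask streams are the declared-fps case the pipeline already
supports. Half the gaze points are drawn near a random object (SD 80 px),
half uniformly over the frame, so all visual-field bands are populated.
An optional isotropic Gaussian gaze noise is applied *before* ground truth
is computed, so truth always describes the emitted track. The generator
emulates geometry, dropout and noise only — not photorealism, tracker
noise spectra, lens distortion or 3D parallax — so passing tests certify
the distance pipeline, not segmentation quality on real video.

### Grid realisation and the rasterization bound

Objects are *realised on the pixel grid* before rasterization: per frame,
the center is rounded to a whole pixel and the radius / half-extents to
whole pixels; masks include the pixels whose centers lie inside the
realised shape, and the analytic ground truth (disk:
$\max(0, \lVert g - c\rVert - r)$; rectangle: distance to the box, 0
inside) describes the realised shape exactly. Agreement between the
pipeline OGD and this closed form then measures pure rasterization error.

The attainable bounds differ by shape, and the difference is fundamental
rather than an implementation artefact. For a grid-realised rectangle the
mask boundary deviates from the box by at most half a pixel per axis, so
$|\mathrm{OGD} - \text{analytic}| \le \sqrt{2}/2$ px always. For a disk no
rasterization rule can achieve $\sqrt{2}/2$ universally under the
pixel-center convention: the Hit rule forces the mask to contain only
centers inside the shape (any center at distance $d > 0$ outside it would
produce Hits with analytic distance up to $\sqrt{2}/2 + d$), yet a point
of a curved boundary can lie ≈ 1.09 px from the nearest in-disk pixel
center (the gap tends to 1 px near the axes as the radius grows, verified
exhaustively over radii 2–60). The provable two-sided disk bound is
$\sqrt{2}$ px, axis-aligned queries are exact, and the median error on
generated scenes is of order $10^{-3}$ px; the test suite asserts the
per-shape bounds, and one acceptance-level check deliberately retains the
stricter half-diagonal target for all shapes and is expected to fail on
rare disk records rather than silently widening the tolerance.

## Numerical and interface choices

* Sentinel value: the exact frame diagonal of the configured camera —
  1600 px is the reference device's special case, not a constant.
* Frame index from time: `floor(x + 0.5)` (half-up) rather than banker's
  rounding, for platform-stable determinism.
* Fixation tables are validated loudly: missing columns are named,
  unsorted input is sorted with a warning, overlapping fixations are a
  hard error naming the ids; no silent row drops anywhere.
* PNG label masks (8-bit, one per frame, JSON label map) and COCO-style
  JSON (polygons with even-odd fill at pixel centers, uncompressed
  column-major RLE; compressed string RLE rejected by name) decode to
  identical masks for the same scene, which the suite checks.
* CSV output of series, curves and events round-trips numerics losslessly.
* All problem sizes in the tests (scene resolutions 160 × 120 to
  1280 × 960, 1 020-record recovery scenes, 25 embedded instances per
  pattern type) are the package's choices to keep the suite fast at desk
  scale while exercising every code path; the bounds they assert are
  resolution-independent.

## Known limitations

* The OGD is 2D image-plane geometry: no depth, parallax or lens
  correction, and saccade samples are out of scope (fixations only).
* Published per-trial pattern counts from the original recordings cannot
  be validated without those recordings; the detectors reproduce the
  described shapes with stated rules, not historical tallies.
* The disk rasterization bound above means exact $\sqrt{2}/2$ closed-form
  agreement should not be expected for curved objects.
* Label-PNG mask streams cannot represent overlapping instances; use the
  COCO reader when instances overlap.
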