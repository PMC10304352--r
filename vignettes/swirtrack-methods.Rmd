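---
title: "Emulating a SWIR real-time insect tracker: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating a SWIR real-time insect tracker: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

swirtrack is a software digital twin of a short-wave infrared (SWIR)
detection system for real-time tracking of flying insects carrying a
photoluminescent tag. The real device couples an InGaAs focal-plane array
(640 x 512 elements, 25 um pitch, 8-bit digitization, 102 full-frame
readouts per second) to programmable logic that extracts the tag position
*while the frame is being read out*. The tag emits at 1400 nm, inside an
atmospheric absorption band, so in daylight the scene is nearly black except
for the tag itself — which is what makes a single threshold comparison per
pixel a sufficient detector. This package reimplements that processing chain
in software, together with a scene simulator that generates ground-truthed
synthetic frame sequences, so that every stage can be exercised and measured
without any hardware or recordings.

## The detection model

During readout, pixels arrive in raster order (row-major: rows top to
bottom, columns left to right). The detector keeps a single stored position.
Each arriving pixel value is compared once against a threshold T in
{0, ..., 255}; if the value is **strictly greater** than T and the pixel is
not flagged hot, the stored position is overwritten with the pixel's 1-based
`(row, col)` coordinates. When the last pixel has been read, the stored
position — the *last* supra-threshold pixel in raster order — is the frame's
result; if no pixel qualified, the reserved sentinel `(0, 0)` is returned.
The 1-based coordinate convention is what makes `(0, 0)` usable as a
sentinel.

`stream_detect()` implements exactly this contract in a compiled
single-pass kernel: one comparison per pixel, constant work per pixel, no
whole-image buffering. An instrumentation mode (`count = TRUE`) reports the
number of comparisons performed, which is always `width x height` — the
constant-work property is what makes the device *hard* real time: the
position is known the moment the last pixel is read, so the worst-case
delay between exposure and output is one readout period, 1/102 s = 9.8 ms.

`latency_and_rates()` carries the corresponding data-rate arithmetic: the
digitized video stream is `640 x 512 x 1 B x 102/s = 33,423,360 B/s`
(about 33.4 decimal MB/s), while the device outputs one waypoint record per
readout. The on-wire encoding of a waypoint is not part of the design we
model; we default to 4 bytes per record (two 16-bit coordinates), which
reproduces the ~0.4 kB/s output figure. MB and kB are decimal throughout.

### Hot pixels

SWIR arrays normally show fixed-pattern hot pixels and small hot-pixel
clusters. Because they are fixed, they need to be identified once and can
simply be skipped during detection — no background subtraction is needed.
The hardware's exclusion mechanism is not documented, so the package models
it behaviourally as a mask (a logical matrix the size of the array).
`calibrate_hot_pixels()` builds the mask from a stack of tag-free dark
frames with an explicit rule of our own design: a pixel is hot iff its value
exceeds `hot_threshold` (default: the detection threshold T) in at least
`min_fraction` (default 0.5) of the frames. The defaults make calibration
conservative in the regime the device operates in — a truly hot pixel sits
at or near saturation in every frame, while background noise (mean 5, sd 2)
essentially never crosses T = 128 — so the rule's two parameters matter only
for marginal, flickering pixels.

## Geometry

All optics are modelled as a distortion-free pinhole. The ground sample
distance (GSD) — world extent covered by one pixel — is
`pitch x distance / focal_length`; `arena_gsd()` provides the companion
empirical form `extent / n_px` (2 m / 512 elements ≈ 3.9 mm) used to size
the tag for the arena setup. The principal point is placed at the array
centre, `((height+1)/2, (width+1)/2)` in 1-based pixel units — the design
does not state it, and the array centre is the only symmetric choice. The
world frame has x along columns, y along rows, z along the optical axis
pointing from the detector into the scene; with the detector 8 m above the
ground and a 2 m tall arena, z ranges over [6, 8] m and the conversion
between pixels and world coordinates assumes z = 7 m (tag halfway up).

Because the true distance is unknown, lateral positions carry a worst-case
error that grows toward the sensor edge: `height_error_bound()` returns
`(half_axis_px x pitch / focal_length) x max(assumed - d_min, d_max -
assumed)` per axis. At 70 mm, 7 m assumed, true distance in [6, 8] m this
gives 11.4 cm in x and 9.1 cm in y. The design documentation quotes a
combined bound of "less than 11.2 cm", which does not follow exactly from
any lens/geometry combination we can reconstruct (70 mm gives 11.4 cm,
50 mm gives 16 cm); we implement the formula and report the discrepancy
rather than reconcile it by tuning.

`fov_exit_budget()` interprets "the shortest path from the centre to the
edge of the field of view" as half the narrow-axis extent
(`min(width, height)/2` pixels), and converts the crossing time at a given
flight speed into a sample count at the 102 Hz rate. At 70 mm, 7 m, 8 m/s
this yields 0.64 m, 80 ms and 8 samples; the device documentation quotes
"approx. 85 ms" for the same configuration, which back-implies an object
distance near 7.4 m. Both the literal-interval form (`sample_budget(0.085,
102)` = 8) and the derived form are provided; the derived exit time is not
used as an acceptance quantity for exactly this reason.

## The tracker

`track_stream()` converts the per-frame detection stream into a waypoint
track at the sampling rate. The fill rule is the one the real system uses:
if no position could be determined (occlusion, roll, perching), the last
known waypoint is taken as the current one (`HELD`). Before the first
detection no position exists, and we deliberately refuse to invent one: such
waypoints are `NO_FIX` with the sentinel retained. Held positions are never
expired, however long the gap — the real system behaved the same way during
long feeder visits, and any expiry horizon would be an invention. Waypoint
`k` of `N` carries the relative timestamp `k/(N-1)`, 0 at track start and 1
at track end, computed over indices rather than wall-clock times because
frame spacing is uniform. Track duration is defined as
`n_waypoints / sample_rate` (each waypoint covers one readout period), so a
track's waypoints-per-second is exactly the sampling rate.

`summarize_track()` reports composition (FIX/HELD/NO_FIX counts and
fractions), the longest held gap, and — when world coordinates are attached
— per-step speeds over consecutive FIX-to-FIX pairs. Speeds are planar (x,
y at the assumed distance); vertical motion is invisible to a single
downward-looking detector.

## The scene simulator

`scene_config()` bundles the study conditions, which are also its defaults:
the 640 x 512 @ 102 Hz detector with T = 128 (mid-scale; the blob saturates
near 255 while background noise lives at 5 ± 2, so the exact value is
uncritical across a wide band), the 70 mm lens, the 2 m cube arena viewed
from 8 m with 7 m assumed distance, a 5 mm tag (2.5 mm radius), mean flight
speed 7.1 m/s (the reported mean bumblebee flight speed), background noise
mean 5 / sd 2 grey levels, and 20 single hot pixels plus 3 2x2 clusters.
Values the design does not pin down were chosen once as field-plausible and
documented here: speed sd 1.5 m/s (bumblebee flights vary substantially
around their mean), heading perturbation sd 0.2 rad per 9.8 ms step (a
maneuverable but not erratic flier), roll sd 0.3 rad with a 1% per-frame
chance of an excursion beyond 90 degrees lasting a few frames (brief roll
maneuvers that turn the tag away), and a tag peak intensity of 255 at the
7 m reference distance (the tag's absolute radiometry is not documented;
saturation at working distance matches the qualitative description of the
signal).

The components are:

* **Trajectory** (`simulate_trajectory()`): a correlated random walk.
  Per step, speed ~ N(7.1, 1.5) truncated at 0 (implemented by clamping;
  at these parameters the truncated mass is ~10^-6), heading perturbed by
  N(0, 0.2 rad), and a vertical inclination drawn with half the heading sd
  so altitude changes are gentler than turns. Positions reflect at the
  arena walls, floor and ceiling. Perch intervals pin the position.
* **Projection**: the continuous pixel position of the tag is
  `world_to_pixel()` at the *true* distance z; the tracker later converts
  back at the *assumed* 7 m, which is exactly how the height-uncertainty
  error arises in the real system.
* **Blob** (`render_frame()`): an isotropic Gaussian with spatial sigma
  `max(0.5 px, tag_radius / GSD(z))` — the point-spread function of the
  real optics is not documented, and a Gaussian subsumes both diffraction
  and mild defocus. Peak amplitude follows
  `tag_peak_intensity x (reference_distance / z)^2 x cos(roll)`, an
  inverse-square distance law with foreshortening, clamped at 0: at
  |roll| >= 90 degrees the tag contributes nothing, which is also the
  visibility criterion in the ground truth.
* **Background**: per-pixel Gaussian read noise, clipped to [0, 255] and
  quantized. The 1400 nm absorption window justifies reducing the whole
  atmospheric radiative problem to this one low-level noise term. The one
  documented false-positive source (specular solar reflections) is out of
  numeric scope.
* **Hot pixels** (`simulate_hot_pixels()`): fixed-pattern, set to 255 in
  every frame including dark frames.
* **Quantization**: clip to [0, 255], round half-up (`floor(x + 0.5)`;
  R's own `round()` is round-half-even, which would bias the comparison
  against a hardware ADC).

Randomness is split into documented sub-streams of the master seed
(trajectory `seed+1`, hot pixels `seed+2`, frame noise `seed+3`, dark
frames `seed+4`), so a sequence re-rendered from the same seed is
byte-identical, and the trajectory can be regenerated without re-rendering
frames.

`render_sequence()` writes the full artifact set to disk (binary PGM
frames, dark frames, mask as PGM and CSV, ground-truth CSV, manifest);
`track_scene()` runs the same chain in memory, rendering each frame,
detecting on it and discarding it — mirroring the real pipeline, in which
only the per-frame position ever leaves the device.

### What the simulator does and does not emulate

The generator reproduces the *detection-relevant* structure of the real
scene: a dark quantized background, fixed-pattern hot pixels, a small
bright blob whose position, size and brightness follow the 3-D geometry,
and dropouts from occlusion, perching and roll. It does not model the PbS
quantum-dot emission spectrum, atmospheric radiative transfer, lens
distortion, depth-of-field blur (beyond the blob sigma floor), motion blur
within an exposure, or solar glare. Tests passing on synthetic scenes
therefore validate the *processing chain* — detector, calibration, tracker,
geometry — under the stated scene model; they do not certify detection
performance on real recordings, where tag radiometry and background
structure are harsher.

## Numerical and testing choices

Thresholds are strict (`>`), matching the stated comparison; coordinates
are 1-based throughout with `(0,0)` reserved; degenerate inputs (empty
detection streams, single-waypoint tracks, a blob projecting partly or
fully off-sensor, zero-noise backgrounds) are defined rather than
accidental. The streaming detector is verified against an independently
written brute-force oracle (vectorised whole-image scan) on tens of
thousands of random frames, masks and thresholds. End-to-end tests check
that wherever the ground truth says the tag was visible, on-sensor and
bright enough to clear T, the detected pixel lies within the blob support
(3 sigma + 1 pixel) of the true projection, and that a level flight at the
assumed distance recovers the simulated 7.1 m/s mean speed within 5%.

Problem sizes in the test-suite were chosen to exercise the full study
geometry where the quantity depends on it (full 640 x 512 frames for the
specificity and waypoint-rate checks: 1,000 and 1,020 frames respectively)
and a coarse 64 x 48 array (10x pitch, tag scaled to keep its blob ~1 px,
i.e. the full-resolution blob geometry) for the many structural and
round-trip tests where resolution is irrelevant.

## Known limitations

* The simulator's free parameters (speed sd, turning sd, roll model, tag
  intensity) are plausibility choices, not fits to recorded flights.
* Intensity modelling is radiometrically uncalibrated; only relative laws
  (inverse-square, foreshortening) are meaningful.
* The tracker is single-target by design, as is the device.
* The 11.2 cm error bound and 85 ms exit time quoted for the original
  setup cannot be reproduced exactly from the documented inputs (see the
  geometry section); the package reports its derivable values, 11.4 cm and
  80 ms, alongside the formulas.
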