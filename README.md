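# swirtrack

A software digital twin of a short-wave infrared (SWIR) real-time tracking
system for flying insects.

Small insects are hard to track outdoors: radio tags are too heavy, video
tracking needs a constant background and reacts too slowly. One way around
both problems is to glue a lightweight photoluminescent tag (lead-sulfide
quantum dots emitting at 1400 nm) to the insect and watch it with an InGaAs
camera through a narrow band-pass filter. 1400 nm sits inside an
atmospheric absorption band, so sunlight barely reaches the ground at that
wavelength and the daytime scene is nearly black — except for the tag. The
position of the brightest object can then be extracted with a single
threshold comparison per pixel, *during* the sensor readout, giving a
hard-real-time tracker: one waypoint per readout with a worst-case delay of
one readout period.

swirtrack reimplements that processing chain in R, together with a
ground-truthed scene simulator, so the whole design can be exercised,
measured and stress-tested without hardware:

* **Streaming detector** — `stream_detect()` scans a frame once in raster
  order and returns the last pixel strictly above the threshold T (not
  flagged hot), or the sentinel `(0, 0)`. For a frame of `W x H` pixels it
  performs exactly `W x H` comparisons (compiled kernel, instrumentation
  mode available), which is what bounds the delay at one readout period:

  `worst_case_delay = 1 / f_s`,  `raw rate = W * H * 1 B * f_s`,

  i.e. 9.8 ms and 33.4 MB/s at 640 x 512 @ 102 Hz, against ~0.4 kB/s of
  waypoint output.
* **Hot-pixel calibration** — `calibrate_hot_pixels()` flags fixed-pattern
  hot pixels from tag-free dark frames (hot in ≥ `min_fraction` of frames);
  they are skipped during detection, making background subtraction
  unnecessary.
* **Tracker** — `track_stream()` turns the detection stream into waypoints
  at the sampling rate with the last-known-position fill rule
  (`FIX`/`HELD`/`NO_FIX`) and relative timestamps in [0, 1];
  `summarize_track()` reports composition, gaps and FIX-to-FIX speeds.
* **Geometry** — pinhole optics: ground sample distance
  `GSD = pitch * d / f`, pixel/world conversion at an assumed distance,
  worst-case position error from unknown height, field-of-view exit budget,
  latency-induced inaccuracy `v * delay`.
* **Simulator** — `scene_config()` + `track_scene()` /
  `render_sequence()`: a correlated-random-walk 3-D flight in a 2 m arena
  viewed from 8 m, projected to the sensor, rendered as a Gaussian blob
  with inverse-square-distance and cos(roll) intensity, over quantized
  background noise and fixed-pattern hot pixels, with
  occlusion/perch/roll dropouts — fully reproducible from one seed.

Frames travel as binary PGM (P5, maxval 255), masks as PGM or `(row,col)`
CSV, tracks as CSV, configurations as flat `key = value` files.

## Worked example

Simulate a 2 s bumblebee-like flight under the study conditions (640 x 512
@ 102 Hz, 70 mm lens, T = 128, tag at 7.1 m/s mean speed) and run the full
calibrate-detect-track chain in memory:

```r
library(swirtrack)

scene <- scene_config(duration_s = 2, seed = 11)
res   <- track_scene(scene)
summarize_track(res$track)
#> <track_summary> 204 waypoints over 2.000 s (102 waypoints/s)
#>   FIX 102 (50.0%) | HELD 102 (50.0%) | NO_FIX 0 (0.0%)
#>   longest held gap: 42 frames (0.412 s)
#>   mean FIX-to-FIX speed: 6.982 m/s
```

One waypoint per readout (102 per second), as the hard-real-time design
requires. Half the waypoints are `HELD`: the 70 mm lens sees only a
1.6 m x 1.28 m window of the 2 m arena at the assumed 7 m distance, so the
simulated insect regularly leaves the field of view (and occasionally rolls
away from the detector) and the tracker repeats the last known position —
the same behaviour the real device shows at a feeder visit. Over the
frames with fresh fixes, the recovered mean speed (6.98 m/s) matches the
simulated 7.1 m/s within a few percent; the residual comes from pixel
quantization and view exits.

The geometry report prints the design figures for the same configuration:

```r
print_key_values(geometry_report(optics_config(70), detector_config(),
                                 arena_config(), speed_mps = 8))
#> gsd_mm_per_px = 2.5
#> arena_gsd_mm_per_px = 3.90625
#> fov_width_m = 1.6
#> fov_height_m = 1.28
#> x_error_m = 0.114285714285714
#> y_error_m = 0.0914285714285714
#> half_extent_m = 0.64
#> exit_time_ms = 80
#> exit_samples = 8
#> latency_inaccuracy_m = 0.0784313725490196
#> readout_period_ms = 9.80392156862745
#> worst_case_delay_ms = 9.80392156862745
#> raw_rate_MBps = 33.42336
#> output_rate_kBps = 0.408
```

A command-line front end wraps the same functions
(`simulate | calibrate | track | summarize | geom | pipeline`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/swird.R", package="swirtrack"))')" \
    geom --machine
```

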