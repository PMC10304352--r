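#' Scene configuration for the synthetic-sequence simulator
#'
#' Bundles everything needed to generate a ground-truthed synthetic detector
#' sequence: the arena/optics/detector geometry, the photoluminescent tag's
#' size and brightness, background noise, fixed-pattern hot pixels, the
#' flight model, occlusion/perch events, duration and the master seed.
#'
#' Defaults reproduce the study conditions of the emulated setup: a 5 mm tag
#' (2.5 mm radius) flying at a mean speed of 7.1 m/s (the mean bumblebee
#' flight speed) in a 2 m cube arena viewed from 8 m through a 70 mm lens at
#' 102 Hz, over a near-dark background (the 1400 nm atmospheric absorption
#' window leaves only sensor read noise: mean grey 5, sd 2), with 20 single
#' hot pixels and 3 2x2 hot-pixel clusters.
#'
#' Randomness is split into documented sub-streams derived from the master
#' seed, so each concern is independently reproducible: trajectory
#' (`seed + 1`), hot-pixel pattern (`seed + 2`), frame background noise
#' (`seed + 3`), dark calibration frames (`seed + 4`).
#'
#' @param arena an [arena_config()].
#' @param optics an [optics_config()].
#' @param detector a [detector_config()].
#' @param tag_radius_m tag radius, metres (default 2.5 mm: a 5 mm disc).
#' @param tag_peak_intensity blob peak grey level at `reference_distance_m`,
#'   face-on roll.
#' @param reference_distance_m distance at which `tag_peak_intensity` holds.
#' @param background_mean,background_sd background grey-level mean and sd
#'   before clipping.
#' @param n_hot_single number of isolated hot pixels.
#' @param n_hot_clusters number of 2x2 hot-pixel clusters.
#' @param n_dark number of tag-free dark frames generated for calibration.
#' @param speed_mean_mps,speed_sd_mps flight-speed distribution, m/s
#'   (truncated at 0).
#' @param turning_sd_rad sd of the per-step heading perturbation, radians.
#' @param roll_sd_rad sd of the baseline roll angle, radians.
#' @param roll_excursion_prob per-frame probability of starting a roll
#'   excursion beyond 90 degrees (tag turned away from the detector).
#' @param occlusion_events list of `c(start_s, end_s)` intervals during which
#'   the tag is occluded (invisible) but keeps moving.
#' @param perch_events list of `c(start_s, end_s)` intervals during which the
#'   animal perches: invisible and stationary.
#' @param duration_s sequence duration, seconds.
#' @param seed master seed (integer).
#' @return an object of class `scene_config`.
#' @examples
#' scene_config(duration_s = 1, seed = 7)
#' @export
scene_config <- function(arena = arena_config(), optics = optics_config(),
                         detector = detector_config(),
                         tag_radius_m = 0.0025, tag_peak_intensity = 255,
                         reference_distance_m = arena$assumed_distance_m,
                         background_mean = 5, background_sd = 2,
                         n_hot_single = 20L, n_hot_clusters = 3L,
                         n_dark = 10L,
                         speed_mean_mps = 7.1, speed_sd_mps = 1.5,
                         turning_sd_rad = 0.2, roll_sd_rad = 0.3,
                         roll_excursion_prob = 0.01,
                         occlusion_events = list(), perch_events = list(),
                         duration_s = 10, seed = 1L) {
  if (tag_radius_m <= 0)
    stop("invalid-config: tag_radius_m must be > 0", call. = FALSE)
  if (duration_s <= 0)
    stop("invalid-config: duration_s must be > 0", call. = FALSE)
  if (tag_peak_intensity < 0 || tag_peak_intensity > detector$grey_max)
    stop("invalid-config: tag_peak_intensity must lie in the grey range",
         call. = FALSE)
  if (background_mean - 3 * background_sd < -detector$grey_max ||
      background_mean + 3 * background_sd > 2 * detector$grey_max)
    stop("invalid-config: background distribution far outside the grey range",
         call. = FALSE)
  if (speed_mean_mps < 0 || speed_sd_mps < 0)
    stop("invalid-config: speed parameters must be >= 0", call. = FALSE)
  for (ev in c(occlusion_events, perch_events))
    if (length(ev) != 2L || ev[1] > ev[2])
      stop("invalid-config: events must be c(start_s, end_s) with start <= end",
           call. = FALSE)
  structure(list(arena = arena, optics = optics, detector = detector,
                 tag_radius_m = tag_radius_m,
                 tag_peak_intensity = tag_peak_intensity,
                 reference_distance_m = reference_distance_m,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 n_hot_single = as.integer(n_hot_single),
                 n_hot_clusters = as.integer(n_hot_clusters),
                 n_dark = as.integer(n_dark),
                 speed_mean_mps = speed_mean_mps,
                 speed_sd_mps = speed_sd_mps,
                 turning_sd_rad = turning_sd_rad,
                 roll_sd_rad = roll_sd_rad,
                 roll_excursion_prob = roll_excursion_prob,
                 occlusion_events = occlusion_events,
                 perch_events = perch_events,
                 duration_s = duration_s, seed = as.integer(seed)),
            class = "scene_config")
}

n_frames <- function(scene) {
  as.integer(round(scene$duration_s * scene$detector$sample_rate_hz))
}

in_interval <- function(t, events) {
  if (length(events) == 0L) return(rep(FALSE, length(t)))
  hit <- rep(FALSE, length(t))
  for (ev in events) hit <- hit | (t >= ev[1] & t <= ev[2])
  hit
}

#' Simulate a fixed-pattern hot-pixel map
#'
#' Draws `n_hot_single` isolated hot pixels and `n_hot_clusters` 2x2 blocks
#' at uniform random in-bounds locations (stream `seed + 2`). Hot pixels are
#' fixed-pattern: the same map applies to every frame of a sequence,
#' including the dark calibration frames.
#'
#' @param scene a [scene_config()].
#' @return a logical hot-pixel matrix (see [hot_mask()]).
#' @export
simulate_hot_pixels <- function(scene) {
  det <- scene$detector
  mask <- empty_mask(det)
  with_seed(scene$seed + 2L, {
    if (scene$n_hot_single > 0L) {
      r <- sample.int(det$height_px, scene$n_hot_single, replace = TRUE)
      cc <- sample.int(det$width_px, scene$n_hot_single, replace = TRUE)
      mask[cbind(r, cc)] <- TRUE
    }
    if (scene$n_hot_clusters > 0L) {
      r <- sample.int(det$height_px - 1L, scene$n_hot_clusters, replace = TRUE)
      cc <- sample.int(det$width_px - 1L, scene$n_hot_clusters, replace = TRUE)
      for (k in seq_len(scene$n_hot_clusters))
        mask[r[k]:(r[k] + 1L), cc[k]:(cc[k] + 1L)] <- TRUE
    }
  })
  mask
}

# evaluate expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Simulate a 3-D flight trajectory
#'
#' A correlated random walk sampled at the detector rate: per step the speed
#' is drawn from a normal distribution truncated at zero, the horizontal
#' heading is perturbed by a normal turning angle, and a bounded vertical
#' component keeps the altitude inside the arena; positions are reflected at
#' the arena walls. The roll angle is drawn around zero with occasional
#' excursions beyond 90 degrees, emulating flight manoeuvres that turn the
#' tag away from the detector. The world frame has x/y lateral (origin on
#' the optical axis), z the distance from the detector along the optical
#' axis, so the arena floor is at `z = detector_height` and the ceiling at
#' `z = detector_height - height`.
#'
#' Visibility is `FALSE` during occlusion or perch events and whenever
#' `|roll| >= 90` degrees. The walk starts at the arena centre, halfway up.
#' Fully reproducible from the scene seed (stream `seed + 1`).
#'
#' @param scene a [scene_config()].
#' @return a `true_trajectory`: data frame with columns `frame_index`
#'   (0-based), `time_s`, `x_m`, `y_m`, `z_m`, `roll_rad`, `visible`,
#'   `true_row`, `true_col` (continuous projected pixel coordinates at the
#'   true distance).
#' @export
simulate_trajectory <- function(scene) {
  det <- scene$detector; arena <- scene$arena
  n <- n_frames(scene)
  if (n < 1L) stop("invalid-config: duration too short for one frame",
                   call. = FALSE)
  dt <- 1 / det$sample_rate_hz
  half <- arena$side_length_m / 2
  z_min <- arena$detector_height_m - arena$height_m
  z_max <- arena$detector_height_m
  t <- (seq_len(n) - 1L) * dt
  occluded <- in_interval(t, scene$occlusion_events)
  perched <- in_interval(t, scene$perch_events)

  x <- numeric(n); y <- numeric(n); z <- numeric(n); roll <- numeric(n)
  with_seed(scene$seed + 1L, {
    x[1] <- 0; y[1] <- 0; z[1] <- (z_min + z_max) / 2
    heading <- runif(1, 0, 2 * pi)
    excursion_left <- 0L; excursion_roll <- 0
    for (k in seq_len(n)) {
      if (k > 1L) {
        if (perched[k]) {
          x[k] <- x[k - 1]; y[k] <- y[k - 1]; z[k] <- z[k - 1]
        } else {
          speed <- max(0, rnorm(1, scene$speed_mean_mps, scene$speed_sd_mps))
          heading <- heading + rnorm(1, 0, scene$turning_sd_rad)
          pitch <- rnorm(1, 0, scene$turning_sd_rad / 2)
          step <- speed * dt
          x[k] <- x[k - 1] + step * cos(pitch) * cos(heading)
          y[k] <- y[k - 1] + step * cos(pitch) * sin(heading)
          z[k] <- z[k - 1] + step * sin(pitch)
          # reflect at the arena walls, ceiling and floor
          if (x[k] > half) { x[k] <- 2 * half - x[k]; heading <- pi - heading }
          if (x[k] < -half) { x[k] <- -2 * half - x[k]; heading <- pi - heading }
          if (y[k] > half) { y[k] <- 2 * half - y[k]; heading <- -heading }
          if (y[k] < -half) { y[k] <- -2 * half - y[k]; heading <- -heading }
          if (z[k] > z_max) z[k] <- 2 * z_max - z[k]
          if (z[k] < z_min) z[k] <- 2 * z_min - z[k]
          x[k] <- min(half, max(-half, x[k]))
          y[k] <- min(half, max(-half, y[k]))
          z[k] <- min(z_max, max(z_min, z[k]))
        }
      }
      if (excursion_left > 0L) {
        roll[k] <- excursion_roll
        excursion_left <- excursion_left - 1L
      } else {
        roll[k] <- rnorm(1, 0, scene$roll_sd_rad)
        if (scene$roll_excursion_prob > 0 &&
            runif(1) < scene$roll_excursion_prob) {
          excursion_left <- as.integer(ceiling(runif(1, 1, 8)))
          excursion_roll <- sample(c(-1, 1), 1) * runif(1, pi / 2, pi)
        }
      }
    }
  })

  visible <- !occluded & !perched & abs(roll) < pi / 2
  px <- t(vapply(seq_len(n), function(k)
    world_to_pixel(x[k], y[k], scene$optics, det, z[k]), numeric(2)))
  structure(data.frame(frame_index = seq_len(n) - 1L, time_s = t,
                       x_m = x, y_m = y, z_m = z, roll_rad = roll,
                       visible = visible,
                       true_row = px[, 1], true_col = px[, 2]),
            class = c("true_trajectory", "data.frame"))
}

round_half_up <- function(x) floor(x + 0.5)

clamp_grey <- function(x, grey_max = 255L) {
  storage.mode(x) <- "integer"
  x[x < 0L] <- 0L
  x[x > grey_max] <- grey_max
  x
}

# Gaussian blob parameters for a trajectory sample; amplitude follows an
# inverse-square distance law times cos(roll) foreshortening (clamped at 0),
# the footprint is the tag radius expressed in pixels at the true distance.
blob_params <- function(point, scene) {
  gsd <- ground_sample_distance(scene$detector$pixel_pitch_um,
                                scene$optics$focal_length_mm, point$z_m)
  list(sigma = max(0.5, scene$tag_radius_m / gsd),
       amplitude = scene$tag_peak_intensity *
         (scene$reference_distance_m / point$z_m)^2 *
         max(0, cos(point$roll_rad)))
}

#' Render one synthetic detector frame
#'
#' Draws per-pixel Gaussian background noise (clipped to the grey range and
#' rounded half-up), adds — if the tag is visible — an isotropic Gaussian
#' blob centred at the projected tag position with footprint
#' `sigma = max(0.5 px, tag_radius / GSD(z))` and peak amplitude
#' `tag_peak_intensity * (reference_distance / z)^2 * cos(roll)` (clamped at
#' 0), sets the hot pixels to the grey maximum, and clips/quantizes to 8
#' bit. Background noise is drawn from R's current RNG stream, so a
#' sequence of calls is reproducible after a single `set.seed()`.
#'
#' @param point one trajectory sample: a one-row data frame or list with
#'   `x_m`, `y_m`, `z_m`, `roll_rad`, `visible`.
#' @param scene a [scene_config()].
#' @param hot logical hot-pixel matrix (see [simulate_hot_pixels()]), or
#'   `NULL` for none.
#' @return an integer matrix `height_px x width_px`, values in `[0, 255]`.
#' @export
render_frame <- function(point, scene, hot = NULL) {
  det <- scene$detector; arena <- scene$arena
  half <- arena$side_length_m / 2
  if (abs(point$x_m) > half + 1e-9 || abs(point$y_m) > half + 1e-9 ||
      point$z_m < arena$detector_height_m - arena$height_m - 1e-9 ||
      point$z_m > arena$detector_height_m + 1e-9)
    stop("invalid-input: trajectory point outside the arena", call. = FALSE)
  vals <- matrix(rnorm(det$height_px * det$width_px,
                       scene$background_mean, scene$background_sd),
                 nrow = det$height_px)
  vals <- clamp_grey(round_half_up(vals), det$grey_max)
  if (isTRUE(point$visible)) {
    bp <- blob_params(point, scene)
    if (bp$amplitude > 0) {
      ctr <- world_to_pixel(point$x_m, point$y_m, scene$optics, det, point$z_m)
      rad <- ceiling(4 * bp$sigma)
      r_lo <- max(1L, as.integer(floor(ctr[["row"]] - rad)))
      r_hi <- min(det$height_px, as.integer(ceiling(ctr[["row"]] + rad)))
      c_lo <- max(1L, as.integer(floor(ctr[["col"]] - rad)))
      c_hi <- min(det$width_px, as.integer(ceiling(ctr[["col"]] + rad)))
      # the tag may project (partly) outside the sensor: render what overlaps
      if (r_lo <= r_hi && c_lo <= c_hi) {
        rows <- r_lo:r_hi; cols <- c_lo:c_hi
        dr <- rows - ctr[["row"]]; dc <- cols - ctr[["col"]]
        blob <- bp$amplitude *
          exp(-outer(dr^2, dc^2, `+`) / (2 * bp$sigma^2))
        vals[rows, cols] <- clamp_grey(
          round_half_up(vals[rows, cols] + blob), det$grey_max)
      }
    }
  }
  if (!is.null(hot)) vals[hot] <- det$grey_max
  vals
}

# render a tag-free frame (background + hot pixels only)
render_dark_frame <- function(scene, hot = NULL) {
  det <- scene$detector
  vals <- matrix(rnorm(det$height_px * det$width_px,
                       scene$background_mean, scene$background_sd),
                 nrow = det$height_px)
  vals <- clamp_grey(round_half_up(vals), det$grey_max)
  if (!is.null(hot)) vals[hot] <- det$grey_max
  vals
}

#' Render a full synthetic sequence to disk
#'
#' Writes `duration * sample_rate` tag-bearing frames as binary PGM files
#' with zero-padded numeric names, `n_dark` tag-free dark frames for
#' hot-pixel calibration, the hot-pixel map (PGM and CSV), the ground-truth
#' trajectory CSV and a manifest of every parameter used. Byte-identical
#' across reruns with the same scene seed.
#'
#' @param scene a [scene_config()].
#' @param dir output directory, created if missing.
#' @return invisibly, a list with `frame_paths`, `dark_paths`, `mask_path`,
#'   `truth_path`, `manifest_path`, `trajectory` and `hot`.
#' @export
render_sequence <- function(scene, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2L) != 0L)
    stop("I/O error: cannot write to directory ", dir, call. = FALSE)
  frames_dir <- file.path(dir, "frames")
  dark_dir <- file.path(dir, "dark")
  dir.create(frames_dir, showWarnings = FALSE)
  dir.create(dark_dir, showWarnings = FALSE)

  hot <- simulate_hot_pixels(scene)
  traj <- simulate_trajectory(scene)
  n <- nrow(traj)
  width <- max(6L, nchar(as.character(n)))
  frame_paths <- file.path(frames_dir,
                           sprintf("frame_%0*d.pgm", width, seq_len(n)))
  with_seed(scene$seed + 3L, {
    for (k in seq_len(n))
      write_pgm(render_frame(traj[k, ], scene, hot), frame_paths[k])
  })
  dark_paths <- file.path(dark_dir,
                          sprintf("dark_%04d.pgm", seq_len(scene$n_dark)))
  with_seed(scene$seed + 4L, {
    for (k in seq_len(scene$n_dark))
      write_pgm(render_dark_frame(scene, hot), dark_paths[k])
  })
  mask_path <- file.path(dir, "hot_mask.pgm")
  write_mask_pgm(hot, mask_path)
  write_mask_csv(hot, file.path(dir, "hot_mask.csv"))
  truth_path <- file.path(dir, "truth.csv")
  write_trajectory(traj, truth_path)
  manifest_path <- file.path(dir, "manifest.txt")
  write_manifest(scene_to_config(scene), manifest_path)
  invisible(list(frame_paths = frame_paths, dark_paths = dark_paths,
                 mask_path = mask_path, truth_path = truth_path,
                 manifest_path = manifest_path,
                 trajectory = traj, hot = hot))
}

#' Write / read a ground-truth trajectory CSV
#'
#' @param traj a `true_trajectory` from [simulate_trajectory()].
#' @param path CSV file path.
#' @return `read_trajectory()` returns a `true_trajectory`;
#'   `write_trajectory()` returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  df$visible <- as.integer(df$visible)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$visible <- as.logical(df$visible)
  structure(df, class = c("true_trajectory", "data.frame"))
}

#' Run the full detection chain on a simulated scene in memory
#'
#' The end-to-end digital twin: simulates the hot-pixel pattern, trajectory
#' and dark frames, calibrates the hot-pixel mask from the dark frames, then
#' renders each frame in turn, runs the streaming detector on it and
#' discards it — frames are never accumulated, mirroring the real system in
#' which only the per-frame position leaves the detector. The detection
#' stream is finally assembled into a waypoint track.
#'
#' @param scene a [scene_config()].
#' @param with_world attach world coordinates (at the arena's assumed
#'   distance) to the track.
#' @return a list with `track` (a `swird_track`), `detections` (data frame
#'   `frame_index`, `row`, `col`), `trajectory` (ground truth), `mask`
#'   (calibrated hot-pixel mask) and `hot` (true hot-pixel map).
#' @export
track_scene <- function(scene, with_world = TRUE) {
  det <- scene$detector
  hot <- simulate_hot_pixels(scene)
  traj <- simulate_trajectory(scene)
  dark <- with_seed(scene$seed + 4L,
                    replicate(scene$n_dark, render_dark_frame(scene, hot),
                              simplify = FALSE))
  mask <- calibrate_hot_pixels(dark, det)
  n <- nrow(traj)
  rows <- integer(n); cols <- integer(n)
  with_seed(scene$seed + 3L, {
    for (k in seq_len(n)) {
      pos <- stream_detect(render_frame(traj[k, ], scene, hot), mask, det)
      rows[k] <- pos[["row"]]; cols[k] <- pos[["col"]]
    }
  })
  detections <- data.frame(frame_index = traj$frame_index,
                           row = rows, col = cols)
  track <- track_stream(detections[, c("row", "col")], det,
                        optics = if (with_world) scene$optics else NULL,
                        assumed_distance_m = scene$arena$assumed_distance_m)
  list(track = track, detections = detections, trajectory = traj,
       mask = mask, hot = hot)
}
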