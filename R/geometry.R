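#' Optics configuration
#'
#' Lens and band-pass filter parameters. The tracking system was operated
#' with 50 mm and 70 mm lenses behind a narrow band-pass filter centred at
#' 1400 nm (25 nm FWHM), inside an atmospheric absorption window so the
#' daytime background is nearly dark.
#'
#' @param focal_length_mm focal length in millimetres.
#' @param filter_center_nm filter central wavelength, nanometres.
#' @param filter_fwhm_nm filter full width at half maximum, nanometres.
#' @param aperture_f_number optional f-number, metadata only.
#' @return an object of class `optics_config`.
#' @export
optics_config <- function(focal_length_mm = 70, filter_center_nm = 1400,
                          filter_fwhm_nm = 25, aperture_f_number = NA_real_) {
  if (!is.finite(focal_length_mm) || focal_length_mm <= 0)
    stop("invalid-config: focal_length_mm must be > 0", call. = FALSE)
  if (filter_center_nm <= 0 || filter_fwhm_nm <= 0)
    stop("invalid-config: filter parameters must be > 0", call. = FALSE)
  structure(list(focal_length_mm = focal_length_mm,
                 filter_center_nm = filter_center_nm,
                 filter_fwhm_nm = filter_fwhm_nm,
                 aperture_f_number = aperture_f_number),
            class = "optics_config")
}

#' Arena configuration
#'
#' Geometry of the outdoor flight arena and the detector mounted above it:
#' a 2 m x 2 m x 2 m net with the detector looking straight down from 8 m.
#' The tag-to-detector distance is unknown during tracking and assumed
#' constant (7 m: tags halfway up the arena).
#'
#' @param side_length_m arena side length, metres.
#' @param height_m arena height, metres.
#' @param detector_height_m detector height above the ground, metres.
#' @param assumed_distance_m object distance assumed when converting pixel
#'   positions to world coordinates, metres.
#' @return an object of class `arena_config`.
#' @export
arena_config <- function(side_length_m = 2, height_m = 2,
                         detector_height_m = 8, assumed_distance_m = 7) {
  if (side_length_m <= 0)
    stop("invalid-config: side_length_m must be > 0", call. = FALSE)
  if (!(height_m > 0 && height_m < detector_height_m))
    stop("invalid-config: need 0 < height_m < detector_height_m", call. = FALSE)
  if (assumed_distance_m < detector_height_m - height_m ||
      assumed_distance_m > detector_height_m)
    stop("invalid-config: assumed_distance_m must lie between detector_height_m - height_m and detector_height_m",
         call. = FALSE)
  structure(list(side_length_m = side_length_m, height_m = height_m,
                 detector_height_m = detector_height_m,
                 assumed_distance_m = assumed_distance_m),
            class = "arena_config")
}

#' Ground sample distance
#'
#' World extent covered by one sensor element at a given object distance,
#' from pinhole similar triangles: `pitch * distance / focal_length`.
#' `arena_gsd()` is the companion empirical form `extent / n_px`, the per-
#' element footprint obtained by dividing a known scene extent by the pixel
#' count that spans it (2 m / 512 elements gives the ~3.9 mm figure for the
#' arena setup).
#'
#' @param pitch_um pixel pitch, micrometres.
#' @param focal_length_mm focal length, millimetres.
#' @param distance_m object distance, metres.
#' @return metres of world extent per pixel.
#' @examples
#' ground_sample_distance(25, 50, 7) * 1e3  # mm per pixel
#' arena_gsd(2, 512) * 1e3                  # ~3.9 mm
#' @export
ground_sample_distance <- function(pitch_um, focal_length_mm, distance_m) {
  if (any(!is.finite(c(pitch_um, focal_length_mm, distance_m))) ||
      any(pitch_um <= 0) || any(focal_length_mm <= 0) || any(distance_m <= 0))
    stop("invalid-input: all arguments must be > 0", call. = FALSE)
  (pitch_um * 1e-6) * distance_m / (focal_length_mm * 1e-3)
}

#' @rdname ground_sample_distance
#' @param extent_m world extent spanned by `n_px` pixels, metres.
#' @param n_px number of pixels spanning the extent.
#' @export
arena_gsd <- function(extent_m, n_px) {
  if (extent_m <= 0 || n_px <= 0)
    stop("invalid-input: all arguments must be > 0", call. = FALSE)
  extent_m / n_px
}

#' Pixel-to-world and world-to-pixel conversion
#'
#' Distortion-free pinhole projection at an assumed object distance. The
#' principal point is at the array centre, `((height+1)/2, (width+1)/2)` in
#' 1-based pixel units; world x runs along sensor columns, y along rows, and
#' z along the optical axis towards the scene. On continuous coordinates the
#' two functions are exact inverses.
#'
#' @param pos a `(row, col)` position (1-based, non-sentinel). `pixel_to_world`
#'   accepts fractional coordinates.
#' @param optics an [optics_config()].
#' @param config a [detector_config()] (supplies pitch and dimensions).
#' @param distance_m assumed object distance along the optical axis, metres.
#' @return `pixel_to_world()`: a named list `(x_m, y_m, z_m)`;
#'   `world_to_pixel()`: a named numeric `c(row =, col =)` in continuous
#'   (unrounded) pixel units.
#' @examples
#' cfg <- detector_config(); opt <- optics_config(70)
#' w <- pixel_to_world(c(row = 256, col = 640), opt, cfg, 7)
#' world_to_pixel(w$x_m, w$y_m, opt, cfg, 7)
#' @export
pixel_to_world <- function(pos, optics, config, distance_m) {
  if (is_sentinel(pos))
    stop("no-fix: the sentinel position has no world coordinates", call. = FALSE)
  if (distance_m <= 0)
    stop("invalid-input: distance_m must be > 0", call. = FALSE)
  gsd <- ground_sample_distance(config$pixel_pitch_um,
                                optics$focal_length_mm, distance_m)
  list(x_m = (pos[["col"]] - (config$width_px + 1) / 2) * gsd,
       y_m = (pos[["row"]] - (config$height_px + 1) / 2) * gsd,
       z_m = distance_m)
}

#' @rdname pixel_to_world
#' @param x_m,y_m lateral world coordinates, metres, origin on the optical
#'   axis at the object plane.
#' @export
world_to_pixel <- function(x_m, y_m, optics, config, distance_m) {
  if (distance_m <= 0)
    stop("invalid-input: distance_m must be > 0", call. = FALSE)
  gsd <- ground_sample_distance(config$pixel_pitch_um,
                                optics$focal_length_mm, distance_m)
  c(row = y_m / gsd + (config$height_px + 1) / 2,
    col = x_m / gsd + (config$width_px + 1) / 2)
}

#' Worst-case position error from unknown object distance
#'
#' Pixel positions are converted to world coordinates at an assumed distance;
#' the true distance lies somewhere in `[d_min, d_max]` (the animal may be
#' anywhere between floor and ceiling). The lateral error is largest at the
#' sensor edge, where the per-axis worst case is
#' `(half_axis_px * pitch / focal_length) * max(assumed - d_min, d_max - assumed)`.
#'
#' @param optics an [optics_config()].
#' @param config a [detector_config()].
#' @param assumed_distance_m distance assumed by the conversion, metres.
#' @param d_min_m,d_max_m bounds on the true distance, metres.
#' @return a named list `(x_error_m, y_error_m)`.
#' @examples
#' height_error_bound(optics_config(70), detector_config(), 7, 6, 8)
#' @export
height_error_bound <- function(optics, config, assumed_distance_m,
                               d_min_m, d_max_m) {
  if (!(d_min_m <= assumed_distance_m && assumed_distance_m <= d_max_m))
    stop("invalid-input: need d_min_m <= assumed_distance_m <= d_max_m",
         call. = FALSE)
  dev <- max(assumed_distance_m - d_min_m, d_max_m - assumed_distance_m)
  scale <- (config$pixel_pitch_um * 1e-6) / (optics$focal_length_mm * 1e-3)
  list(x_error_m = (config$width_px / 2) * scale * dev,
       y_error_m = (config$height_px / 2) * scale * dev)
}

#' Field-of-view exit time and sample buffer
#'
#' How long an insect flying at a given speed takes to cross from the centre
#' of the field of view to its nearest edge (the shortest path, i.e. half the
#' narrow-axis extent), and how many position samples the detector records in
#' that time — the buffer available to a follow-up gimbal controller before
#' tracking is lost. `sample_budget()` is the companion form taking a literal
#' time interval.
#'
#' @param optics an [optics_config()].
#' @param config a [detector_config()].
#' @param distance_m object distance, metres.
#' @param speed_mps flight speed, metres per second.
#' @return a named list `(half_extent_m, exit_time_s, samples)`.
#' @examples
#' fov_exit_budget(optics_config(70), detector_config(), 7, 8)
#' sample_budget(0.085, 102)  # 8 samples
#' @export
fov_exit_budget <- function(optics, config, distance_m, speed_mps) {
  if (!is.finite(speed_mps) || speed_mps <= 0)
    stop("invalid-input: speed_mps must be > 0", call. = FALSE)
  gsd <- ground_sample_distance(config$pixel_pitch_um,
                                optics$focal_length_mm, distance_m)
  half_extent <- min(config$width_px, config$height_px) / 2 * gsd
  exit_time <- half_extent / speed_mps
  list(half_extent_m = half_extent, exit_time_s = exit_time,
       samples = sample_budget(exit_time, config$sample_rate_hz))
}

#' @rdname fov_exit_budget
#' @param interval_s a time interval, seconds.
#' @param rate_hz sampling rate, Hz.
#' @export
sample_budget <- function(interval_s, rate_hz) {
  if (interval_s < 0 || rate_hz <= 0)
    stop("invalid-input: interval_s must be >= 0 and rate_hz > 0", call. = FALSE)
  as.integer(floor(interval_s * rate_hz))
}

#' Latency-induced tracking inaccuracy
#'
#' Distance an animal travels between the moment a frame is exposed and the
#' moment its position is available: `speed * delay`. At the mean bumblebee
#' flight speed of 7.1 m/s, a 40 ms processing delay already corresponds to
#' more than 28 cm of positional inaccuracy.
#'
#' @param speed_mps flight speed, metres per second (>= 0).
#' @param delay_s processing delay, seconds (>= 0).
#' @return inaccuracy in metres.
#' @examples
#' latency_inaccuracy(7.1, 0.040)
#' @export
latency_inaccuracy <- function(speed_mps, delay_s) {
  if (!is.finite(speed_mps) || !is.finite(delay_s) ||
      speed_mps < 0 || delay_s < 0)
    stop("invalid-input: speed_mps and delay_s must be >= 0", call. = FALSE)
  speed_mps * delay_s
}
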