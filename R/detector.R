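#' Detector configuration
#'
#' Describes the focal-plane array and its readout: sensor dimensions, bit
#' depth, pixel pitch, sampling rate and the detection threshold T. Defaults
#' match the InGaAs array used in the tracking system this package emulates:
#' 640 x 512 elements of 25 um pitch, 8-bit digitization, read out 102 times
#' per second.
#'
#' @param width_px sensor width in pixels (columns).
#' @param height_px sensor height in pixels (rows).
#' @param bit_depth bits per pixel after digitization.
#' @param pixel_pitch_um element pitch in micrometres.
#' @param sample_rate_hz full-frame readouts per second.
#' @param threshold detection threshold T, a grey level in
#'   `[0, 2^bit_depth - 1]`; a pixel is a detection iff its value is
#'   *strictly greater* than T.
#' @return an object of class `detector_config`.
#' @examples
#' detector_config()
#' detector_config(width_px = 64, height_px = 48, threshold = 200)
#' @export
detector_config <- function(width_px = 640L, height_px = 512L,
                            bit_depth = 8L, pixel_pitch_um = 25,
                            sample_rate_hz = 102, threshold = 128L) {
  width_px <- as.integer(width_px)
  height_px <- as.integer(height_px)
  bit_depth <- as.integer(bit_depth)
  if (is.na(width_px) || width_px <= 0L || is.na(height_px) || height_px <= 0L)
    stop("invalid-config: width_px and height_px must be positive integers",
         call. = FALSE)
  if (is.na(bit_depth) || bit_depth <= 0L)
    stop("invalid-config: bit_depth must be a positive integer", call. = FALSE)
  if (!is.finite(sample_rate_hz) || sample_rate_hz <= 0)
    stop("invalid-config: sample_rate_hz must be > 0", call. = FALSE)
  if (!is.finite(pixel_pitch_um) || pixel_pitch_um <= 0)
    stop("invalid-config: pixel_pitch_um must be > 0", call. = FALSE)
  threshold <- as.integer(threshold)
  grey_max <- as.integer(2^bit_depth - 1)
  if (is.na(threshold) || threshold < 0L || threshold > grey_max)
    stop("invalid-config: threshold must lie in [0, ", grey_max, "]",
         call. = FALSE)
  structure(list(width_px = width_px, height_px = height_px,
                 bit_depth = bit_depth, pixel_pitch_um = pixel_pitch_um,
                 sample_rate_hz = sample_rate_hz, threshold = threshold,
                 grey_max = grey_max),
            class = "detector_config")
}

#' @export
print.detector_config <- function(x, ...) {
  cat(sprintf("<detector_config> %d x %d px, %d-bit, %.0f um pitch, %g Hz, T = %d\n",
              x$width_px, x$height_px, x$bit_depth, x$pixel_pitch_um,
              x$sample_rate_hz, x$threshold))
  invisible(x)
}

#' Pixel positions and the no-detection sentinel
#'
#' Detection results are 1-based `(row, col)` integer pairs; the reserved
#' value `(0, 0)` is the sentinel meaning "no pixel exceeded the threshold in
#' this frame". `pixel_position()` validates and constructs one,
#' `is_sentinel()` tests for the sentinel.
#'
#' @param row,col 1-based pixel coordinates, or both 0 for the sentinel.
#' @param config optional [detector_config()] for bounds checking.
#' @return a named integer vector `c(row = , col = )`.
#' @examples
#' pixel_position(10, 20)
#' is_sentinel(pixel_position(0, 0))
#' @export
pixel_position <- function(row, col, config = NULL) {
  row <- as.integer(row); col <- as.integer(col)
  if (is.na(row) || is.na(col))
    stop("invalid-input: row/col must be integers", call. = FALSE)
  if (xor(row == 0L, col == 0L) || row < 0L || col < 0L)
    stop("invalid-input: position must be (0,0) or have row >= 1 and col >= 1",
         call. = FALSE)
  if (!is.null(config) && row > 0L &&
      (row > config$height_px || col > config$width_px))
    stop("invalid-input: position outside the sensor", call. = FALSE)
  c(row = row, col = col)
}

#' @rdname pixel_position
#' @param pos a position as returned by [pixel_position()] or [stream_detect()].
#' @export
is_sentinel <- function(pos) {
  pos[[1]] == 0L && pos[[2]] == 0L
}

validate_frame <- function(frame, config) {
  if (!is.matrix(frame))
    stop("invalid-input: frame must be a matrix", call. = FALSE)
  if (nrow(frame) != config$height_px || ncol(frame) != config$width_px)
    stop(sprintf("invalid-input: frame is %d x %d but config expects %d x %d",
                 nrow(frame), ncol(frame), config$height_px, config$width_px),
         call. = FALSE)
  invisible(frame)
}

empty_mask <- function(config) {
  matrix(FALSE, nrow = config$height_px, ncol = config$width_px)
}

#' Hot-pixel masks
#'
#' A hot-pixel mask marks fixed-pattern sensor elements that are excluded
#' from detection. It is represented as a logical matrix of the sensor
#' dimensions (`TRUE` = hot). `hot_mask()` builds one from a two-column
#' `(row, col)` table; `mask_positions()` converts back to the table form.
#'
#' @param positions a matrix or data frame with columns `row`, `col`
#'   (1-based), possibly zero rows.
#' @param config a [detector_config()].
#' @return `hot_mask()`: a logical `height_px x width_px` matrix;
#'   `mask_positions()`: a data frame with columns `row`, `col` in raster
#'   order.
#' @examples
#' cfg <- detector_config(width_px = 8, height_px = 6)
#' m <- hot_mask(data.frame(row = c(1, 5), col = c(1, 7)), cfg)
#' mask_positions(m)
#' @export
hot_mask <- function(positions, config) {
  m <- empty_mask(config)
  if (is.null(positions) || NROW(positions) == 0L) return(m)
  positions <- as.data.frame(positions)
  r <- as.integer(positions$row); cc <- as.integer(positions$col)
  if (any(is.na(r)) || any(is.na(cc)) || any(r < 1L) || any(cc < 1L) ||
      any(r > config$height_px) || any(cc > config$width_px))
    stop("invalid-input: hot-pixel positions must be 1-based and in bounds (sentinel excluded)",
         call. = FALSE)
  m[cbind(r, cc)] <- TRUE
  m
}

#' @rdname hot_mask
#' @param mask a logical hot-pixel matrix.
#' @export
mask_positions <- function(mask) {
  hot <- which(t(mask))          # raster order: transpose, column-major scan
  ncol_ <- nrow(t(mask))
  col <- ((hot - 1L) %% ncol_) + 1L
  row <- ((hot - 1L) %/% ncol_) + 1L
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Streaming threshold detection on one frame
#'
#' Scans the frame once in raster order (row-major: rows top to bottom,
#' columns left to right) exactly as the on-sensor logic does during readout.
#' Each pixel is compared once against the threshold T; a pixel that is
#' strictly greater than T and not flagged hot overwrites the stored
#' position. After the last pixel the stored position is returned; if no
#' pixel qualified, the sentinel `(0, 0)` is returned. The result is thus the
#' *last* supra-threshold unmasked pixel in raster order.
#'
#' The scan performs constant work per pixel — the detection result is
#' available the moment the last pixel has been read, which is what bounds
#' the detector's latency at one readout period. With `count = TRUE` the
#' number of comparisons actually performed is attached; it always equals
#' `width_px * height_px`.
#'
#' @param frame an integer matrix, `height_px x width_px`, values in
#'   `[0, 2^bit_depth - 1]`.
#' @param mask a logical hot-pixel matrix of the same dimensions (see
#'   [hot_mask()]), or `NULL` for no masking.
#' @param config a [detector_config()]; supplies dimensions and threshold T.
#' @param threshold optional override of `config$threshold`.
#' @param count if `TRUE`, attach the comparison count as attribute
#'   `"comparisons"`.
#' @return a named integer vector `c(row =, col =)`; `(0, 0)` is the
#'   no-detection sentinel.
#' @examples
#' cfg <- detector_config(width_px = 6, height_px = 4, threshold = 128)
#' f <- matrix(0L, 4, 6); f[3, 5] <- 255L
#' stream_detect(f, NULL, cfg)
#' @export
stream_detect <- function(frame, mask = NULL, config, threshold = NULL,
                          count = FALSE) {
  validate_frame(frame, config)
  if (is.null(mask)) mask <- empty_mask(config)
  if (!is.logical(mask) || nrow(mask) != config$height_px ||
      ncol(mask) != config$width_px)
    stop("invalid-input: mask must be a logical matrix matching the sensor dimensions",
         call. = FALSE)
  t_eff <- if (is.null(threshold)) config$threshold else as.integer(threshold)
  if (is.na(t_eff) || t_eff < 0L || t_eff > config$grey_max)
    stop("invalid-config: threshold must lie in [0, ", config$grey_max, "]",
         call. = FALSE)
  storage.mode(frame) <- "integer"
  res <- cpp_stream_detect(frame, mask, t_eff)
  out <- c(row = res[[1]], col = res[[2]])
  if (count) attr(out, "comparisons") <- res[[3]]
  out
}

#' Hot-pixel calibration from dark frames
#'
#' Hot pixels are fixed-pattern: they only need to be identified once, after
#' which they are skipped during detection, making background subtraction
#' unnecessary. Calibration takes a stack of tag-free ("dark") frames and
#' flags every pixel whose value exceeds `hot_threshold` in at least
#' `min_fraction` of the frames.
#'
#' @param dark_frames a list of integer matrices, all of the sensor
#'   dimensions, recorded with no tag in view.
#' @param config a [detector_config()].
#' @param hot_threshold grey level above which a pixel counts as hot in one
#'   frame (strictly greater); defaults to the detection threshold T.
#' @param min_fraction minimum fraction of frames, in `[0, 1]`, in which a
#'   pixel must exceed `hot_threshold` to be flagged.
#' @return a logical hot-pixel mask (see [hot_mask()]).
#' @examples
#' cfg <- detector_config(width_px = 8, height_px = 6, threshold = 128)
#' dark <- replicate(10, matrix(0L, 6, 8), simplify = FALSE)
#' for (i in seq_along(dark)) dark[[i]][5, 5] <- 255L
#' mask_positions(calibrate_hot_pixels(dark, cfg))
#' @export
calibrate_hot_pixels <- function(dark_frames, config,
                                 hot_threshold = config$threshold,
                                 min_fraction = 0.5) {
  if (!is.list(dark_frames) || length(dark_frames) == 0L)
    stop("invalid-input: need at least one dark frame", call. = FALSE)
  if (!is.finite(min_fraction) || min_fraction < 0 || min_fraction > 1)
    stop("invalid-input: min_fraction must lie in [0, 1]", call. = FALSE)
  for (f in dark_frames) validate_frame(f, config)
  counts <- Reduce(`+`, lapply(dark_frames, function(f) f > hot_threshold))
  n <- length(dark_frames)
  # a pixel is hot iff it exceeded the threshold in >= min_fraction of frames
  counts / n >= min_fraction & counts > 0L
}

#' Latency and data-rate accounting
#'
#' The detector processes pixels in parallel with the readout, so the tag
#' position is known the moment the last pixel has been read: the worst-case
#' delay between exposure and position output equals one readout period,
#' `1 / sample_rate`. The raw digitized video rate is
#' `width * height * (bit_depth / 8) * sample_rate` bytes per second, while
#' the device outputs only one compact waypoint record per readout.
#' Megabytes and kilobytes are decimal (1e6 and 1e3 bytes).
#'
#' @param config a [detector_config()].
#' @param bytes_per_waypoint size of one output record in bytes; the default
#'   4 corresponds to two 16-bit coordinates.
#' @return an object of class `latency_and_rates`: a list with
#'   `readout_period_s`, `worst_case_delay_s`, `raw_rate_Bps`,
#'   `output_rate_Bps`.
#' @examples
#' lr <- latency_and_rates(detector_config())
#' lr$raw_rate_Bps / 1e6    # ~33.4 MB/s
#' lr$output_rate_Bps / 1e3 # ~0.4 kB/s
#' @export
latency_and_rates <- function(config, bytes_per_waypoint = 4L) {
  bytes_per_waypoint <- as.integer(bytes_per_waypoint)
  if (is.na(bytes_per_waypoint) || bytes_per_waypoint < 1L)
    stop("invalid-config: bytes_per_waypoint must be >= 1", call. = FALSE)
  readout <- 1 / config$sample_rate_hz
  raw <- config$width_px * config$height_px * (config$bit_depth / 8) *
    config$sample_rate_hz
  out <- bytes_per_waypoint * config$sample_rate_hz
  structure(list(readout_period_s = readout,
                 worst_case_delay_s = readout,
                 raw_rate_Bps = raw,
                 output_rate_Bps = out),
            class = "latency_and_rates")
}

#' @export
print.latency_and_rates <- function(x, ...) {
  cat(sprintf(paste0("<latency_and_rates>\n",
                     "  readout period:   %.4f ms\n",
                     "  worst-case delay: %.4f ms\n",
                     "  raw data rate:    %.6g MB/s\n",
                     "  output data rate: %.6g kB/s\n"),
              x$readout_period_s * 1e3, x$worst_case_delay_s * 1e3,
              x$raw_rate_Bps / 1e6, x$output_rate_Bps / 1e3))
  invisible(x)
}
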