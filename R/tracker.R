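#' Build a waypoint track from a detection stream
#'
#' Converts the per-frame detection stream (one `(row, col)` position or
#' sentinel per readout) into a timestamped waypoint track, applying the
#' last-known-position rule: if no position could be determined in a frame,
#' the last known waypoint is taken as the current one.
#'
#' Each input yields exactly one waypoint with one of three statuses:
#' \describe{
#'   \item{FIX}{a fresh detection this frame;}
#'   \item{HELD}{sentinel received, the most recent FIX position repeated;}
#'   \item{NO_FIX}{sentinel received before any detection — the sentinel is
#'     retained, no position is invented.}
#' }
#' Waypoint `k` of `N` carries the relative timestamp `rel_time = k/(N-1)`
#' (0 for a single waypoint): 0 at track start, 1 at track end. When a
#' geometry context (`optics` + `assumed_distance_m`) is given, world
#' coordinates at the assumed distance are attached to FIX/HELD waypoints.
#'
#' @param detections the detection stream: a two-column matrix or data frame
#'   with columns `row`, `col` (1-based, `(0,0)` = sentinel), one row per
#'   frame, in frame order.
#' @param config a [detector_config()]; supplies the sampling rate that
#'   spaces the waypoints in time.
#' @param optics an [optics_config()], or `NULL` to skip world coordinates.
#' @param assumed_distance_m assumed object distance for the pixel-to-world
#'   conversion, metres.
#' @return a `swird_track`: a data frame with columns `frame_index` (0-based),
#'   `time_s`, `row`, `col`, `status`, `x_m`, `y_m`, `rel_time`, and
#'   attribute `sample_rate_hz`. Empty input gives a zero-row track.
#' @examples
#' cfg <- detector_config()
#' det <- rbind(c(10, 10), c(0, 0), c(0, 0), c(12, 11))
#' colnames(det) <- c("row", "col")
#' track_stream(det, cfg)
#' @export
track_stream <- function(detections, config, optics = NULL,
                         assumed_distance_m = 7) {
  if (!is.finite(config$sample_rate_hz) || config$sample_rate_hz <= 0)
    stop("invalid-config: sample_rate_hz must be > 0", call. = FALSE)
  det <- as.data.frame(detections)
  if (ncol(det) >= 2 && !all(c("row", "col") %in% names(det)))
    names(det)[1:2] <- c("row", "col")
  n <- nrow(det)
  track <- data.frame(frame_index = integer(0), time_s = numeric(0),
                      row = integer(0), col = integer(0),
                      status = character(0), x_m = numeric(0),
                      y_m = numeric(0), rel_time = numeric(0))
  if (n > 0L) {
    r_in <- as.integer(det$row); c_in <- as.integer(det$col)
    if (any(is.na(r_in) | is.na(c_in)) || any(xor(r_in == 0L, c_in == 0L)) ||
        any(r_in < 0L | c_in < 0L))
      stop("invalid-input: detections must be 1-based positions or the (0,0) sentinel",
           call. = FALSE)
    row <- integer(n); col <- integer(n); status <- character(n)
    last_r <- 0L; last_c <- 0L
    for (k in seq_len(n)) {
      if (r_in[k] > 0L) {
        last_r <- r_in[k]; last_c <- c_in[k]
        row[k] <- last_r; col[k] <- last_c; status[k] <- "FIX"
      } else if (last_r > 0L) {
        row[k] <- last_r; col[k] <- last_c; status[k] <- "HELD"
      } else {
        row[k] <- 0L; col[k] <- 0L; status[k] <- "NO_FIX"
      }
    }
    idx <- seq_len(n) - 1L
    track <- data.frame(
      frame_index = idx,
      time_s = idx / config$sample_rate_hz,
      row = row, col = col, status = status,
      x_m = NA_real_, y_m = NA_real_,
      rel_time = if (n == 1L) 0 else idx / (n - 1L))
    if (!is.null(optics)) {
      has_pos <- track$status != "NO_FIX"
      if (any(has_pos)) {
        gsd <- ground_sample_distance(config$pixel_pitch_um,
                                      optics$focal_length_mm,
                                      assumed_distance_m)
        track$x_m[has_pos] <- (track$col[has_pos] - (config$width_px + 1) / 2) * gsd
        track$y_m[has_pos] <- (track$row[has_pos] - (config$height_px + 1) / 2) * gsd
      }
    }
  }
  structure(track, sample_rate_hz = config$sample_rate_hz,
            class = c("swird_track", "data.frame"))
}

#' Summarise a waypoint track
#'
#' Reports waypoint count, duration, status composition, the longest run of
#' held (non-detected) waypoints, and — when world coordinates are present —
#' per-step speeds over consecutive FIX-to-FIX waypoint pairs and their mean.
#' Duration is `n_waypoints / sample_rate` (each waypoint covers one readout
#' period), so waypoints-per-second equals the sampling rate.
#'
#' @param track a `swird_track` from [track_stream()] or [read_waypoints()].
#' @return an object of class `track_summary`: a list with `n_waypoints`,
#'   `duration_s`, `waypoints_per_s`, `n_fix`, `n_held`, `n_no_fix`,
#'   `frac_fix`, `frac_held`, `frac_no_fix`, `longest_held_frames`,
#'   `longest_held_s`, and (with world coordinates) `mean_speed_mps` and
#'   `step_speeds_mps`.
#' @examples
#' cfg <- detector_config()
#' det <- rbind(c(10, 10), c(0, 0), c(12, 11))
#' colnames(det) <- c("row", "col")
#' summarize_track(track_stream(det, cfg, optics_config()))
#' @export
summarize_track <- function(track) {
  n <- nrow(track)
  if (n == 0L)
    stop("invalid-input: cannot summarise an empty track", call. = FALSE)
  rate <- attr(track, "sample_rate_hz")
  held <- rle(track$status == "HELD")
  longest_held <- if (any(held$values)) max(held$lengths[held$values]) else 0L
  out <- list(
    n_waypoints = n,
    duration_s = n / rate,
    waypoints_per_s = rate,
    n_fix = sum(track$status == "FIX"),
    n_held = sum(track$status == "HELD"),
    n_no_fix = sum(track$status == "NO_FIX"),
    longest_held_frames = as.integer(longest_held),
    longest_held_s = longest_held / rate)
  out$frac_fix <- out$n_fix / n
  out$frac_held <- out$n_held / n
  out$frac_no_fix <- out$n_no_fix / n
  if (any(!is.na(track$x_m))) {
    fixfix <- which(track$status[-n] == "FIX" & track$status[-1] == "FIX")
    if (length(fixfix) > 0L) {
      dx <- track$x_m[fixfix + 1L] - track$x_m[fixfix]
      dy <- track$y_m[fixfix + 1L] - track$y_m[fixfix]
      out$step_speeds_mps <- sqrt(dx^2 + dy^2) * rate
      out$mean_speed_mps <- mean(out$step_speeds_mps)
    } else {
      out$step_speeds_mps <- numeric(0)
      out$mean_speed_mps <- NA_real_
    }
  }
  structure(out, class = "track_summary")
}

#' @export
print.track_summary <- function(x, ...) {
  cat(sprintf("<track_summary> %d waypoints over %.3f s (%.6g waypoints/s)\n",
              x$n_waypoints, x$duration_s, x$waypoints_per_s))
  cat(sprintf("  FIX %d (%.1f%%) | HELD %d (%.1f%%) | NO_FIX %d (%.1f%%)\n",
              x$n_fix, 100 * x$frac_fix, x$n_held, 100 * x$frac_held,
              x$n_no_fix, 100 * x$frac_no_fix))
  cat(sprintf("  longest held gap: %d frames (%.3f s)\n",
              x$longest_held_frames, x$longest_held_s))
  if (!is.null(x$mean_speed_mps) && !is.na(x$mean_speed_mps))
    cat(sprintf("  mean FIX-to-FIX speed: %.3f m/s\n", x$mean_speed_mps))
  invisible(x)
}

#' Read and write waypoint CSV files
#'
#' The waypoint CSV has the mandatory header
#' `frame_index,time_s,row,col,status,x_m,y_m,rel_time`; the sentinel is
#' written as `0,0` and world fields are left empty when absent. Decimal
#' points are always `.` regardless of locale. A written track re-reads to
#' the same values.
#'
#' @param track a `swird_track`.
#' @param path file path of the CSV.
#' @param sample_rate_hz sampling rate to attach on read; when `NULL`,
#'   inferred from the `time_s` column spacing.
#' @return `read_waypoints()` returns a `swird_track`;
#'   `write_waypoints()` returns `path` invisibly.
#' @export
write_waypoints <- function(track, path) {
  df <- as.data.frame(track)
  df$x_m <- ifelse(is.na(df$x_m), "", sprintf("%.15g", df$x_m))
  df$y_m <- ifelse(is.na(df$y_m), "", sprintf("%.15g", df$y_m))
  old <- Sys.getlocale("LC_NUMERIC")
  on.exit(suppressWarnings(Sys.setlocale("LC_NUMERIC", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_NUMERIC", "C"))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_waypoints
#' @export
read_waypoints <- function(path, sample_rate_hz = NULL) {
  if (!file.exists(path))
    stop("format error: no such waypoint file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_index", "time_s", "row", "col", "status", "x_m", "y_m",
            "rel_time")
  if (!all(need %in% names(df)))
    stop("format error: waypoint CSV ", path, " lacks mandatory columns",
         call. = FALSE)
  if (is.null(sample_rate_hz)) {
    sample_rate_hz <- if (nrow(df) >= 2L)
      1 / (df$time_s[2L] - df$time_s[1L]) else NA_real_
  }
  structure(df[need], sample_rate_hz = sample_rate_hz,
            class = c("swird_track", "data.frame"))
}
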