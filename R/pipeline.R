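#' Run the full simulate / calibrate / track / summarize pipeline
#'
#' Executes the four stages end to end against artifacts on disk: renders a
#' synthetic sequence (frames, dark frames, hot-pixel map, ground truth),
#' calibrates the hot-pixel mask from the dark frames, runs the streaming
#' detector over the rendered frames, assembles the waypoint track, and
#' writes `waypoints.csv`, `summary.txt` and a reproduction manifest to the
#' output directory. A stage failure is re-signalled with the stage name in
#' the diagnostic.
#'
#' @param scene a [scene_config()], or a path to a flat key-value config
#'   file (see [read_run_config()]).
#' @param out_dir output directory, created if missing.
#' @param seed optional seed overriding the scene's.
#' @param verbose print per-stage progress lines.
#' @return invisibly, a list with `track`, `summary`, `mask`, `paths`.
#' @export
run_pipeline <- function(scene, out_dir, seed = NULL, verbose = TRUE) {
  if (is.character(scene))
    scene <- config_to_scene(read_run_config(scene), seed = seed)
  else if (!is.null(seed)) {
    cfg <- scene_to_config(scene)
    cfg[["scene.seed"]] <- seed
    scene <- config_to_scene(cfg)
  }
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  say("simulate: %d frames at %g Hz (seed %d) -> %s",
      n_frames(scene), scene$detector$sample_rate_hz, scene$seed, out_dir)
  t0 <- proc.time()[["elapsed"]]
  art <- stage("simulate", render_sequence(scene, out_dir))
  say("simulate: done in %.1f s", proc.time()[["elapsed"]] - t0)

  say("calibrate: %d dark frames", length(art$dark_paths))
  mask <- stage("calibrate", {
    dark <- lapply(art$dark_paths, read_pgm, config = scene$detector)
    calibrate_hot_pixels(dark, scene$detector)
  })
  say("calibrate: %d hot pixels flagged", sum(mask))
  write_mask_pgm(mask, file.path(out_dir, "calibrated_mask.pgm"))

  say("track: threshold T = %d", scene$detector$threshold)
  track <- stage("track", {
    det <- detect_frames(file.path(out_dir, "frames"), mask, scene$detector)
    track_stream(det[, c("row", "col")], scene$detector,
                 optics = scene$optics,
                 assumed_distance_m = scene$arena$assumed_distance_m)
  })
  wp_path <- file.path(out_dir, "waypoints.csv")
  write_waypoints(track, wp_path)
  say("track: %d waypoints -> %s", nrow(track), wp_path)

  summ <- stage("summarize", summarize_track(track))
  summary_path <- file.path(out_dir, "summary.txt")
  writeLines(utils::capture.output(print(summ)), summary_path)
  say("summarize: %d FIX / %d HELD / %d NO_FIX",
      summ$n_fix, summ$n_held, summ$n_no_fix)

  invisible(list(track = track, summary = summ, mask = mask,
                 paths = list(out_dir = out_dir, waypoints = wp_path,
                              summary = summary_path,
                              manifest = art$manifest_path)))
}

#' Geometry report for a configuration
#'
#' Computes the standard geometry figures for a detector/optics/arena
#' combination: ground sample distance (pinhole and arena-based forms),
#' field-of-view extent at the assumed distance, worst-case position error
#' from the unknown height, field-of-view exit budget, latency-induced
#' inaccuracy, and the latency/data-rate accounting.
#'
#' @param optics an [optics_config()].
#' @param detector a [detector_config()].
#' @param arena an [arena_config()].
#' @param speed_mps flight speed used for the exit budget and latency
#'   inaccuracy, m/s.
#' @return a named list of the computed figures (metres, seconds, bytes per
#'   second), printable as key-value lines with [print_key_values()].
#' @export
geometry_report <- function(optics = optics_config(),
                            detector = detector_config(),
                            arena = arena_config(), speed_mps = 7.1) {
  d <- arena$assumed_distance_m
  gsd <- ground_sample_distance(detector$pixel_pitch_um,
                                optics$focal_length_mm, d)
  err <- height_error_bound(optics, detector, d,
                            arena$detector_height_m - arena$height_m,
                            arena$detector_height_m)
  fov <- fov_exit_budget(optics, detector, d, speed_mps)
  lr <- latency_and_rates(detector)
  list(
    gsd_mm_per_px = gsd * 1e3,
    arena_gsd_mm_per_px = arena_gsd(arena$side_length_m,
                                    min(detector$width_px,
                                        detector$height_px)) * 1e3,
    fov_width_m = detector$width_px * gsd,
    fov_height_m = detector$height_px * gsd,
    x_error_m = err$x_error_m,
    y_error_m = err$y_error_m,
    half_extent_m = fov$half_extent_m,
    exit_time_ms = fov$exit_time_s * 1e3,
    exit_samples = fov$samples,
    latency_inaccuracy_m = latency_inaccuracy(speed_mps,
                                              lr$worst_case_delay_s),
    readout_period_ms = lr$readout_period_s * 1e3,
    worst_case_delay_ms = lr$worst_case_delay_s * 1e3,
    raw_rate_MBps = lr$raw_rate_Bps / 1e6,
    output_rate_kBps = lr$output_rate_Bps / 1e3)
}

#' Print a named list as machine-readable key-value lines
#'
#' @param x a named list of scalars.
#' @param file connection or "" for standard output.
#' @return `x`, invisibly.
#' @export
print_key_values <- function(x, file = "") {
  lines <- vapply(seq_along(x), function(i) {
    v <- x[[i]]
    sprintf("%s = %s", names(x)[i],
            if (is.numeric(v)) sprintf("%.15g", v) else as.character(v))
  }, character(1))
  cat(lines, sep = "\n", file = file)
  if (file == "") cat("\n")
  invisible(x)
}
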