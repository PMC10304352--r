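#' Flat key-value configuration files
#'
#' Run configurations travel as flat `key = value` text files (one pair per
#' line, `#` comments allowed), with dotted keys grouping detector, optics,
#' arena and scene parameters. Values are written with dot decimal points
#' regardless of locale and round-trip without loss. Event lists are encoded
#' as `start:end` pairs separated by `;`.
#'
#' @param path file path.
#' @param config a named list of scalar values (character, numeric, logical).
#' @return `read_run_config()` returns a named list of character values
#'   (use [config_to_scene()] to build a [scene_config()] from it);
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("invalid-input: no such config file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad))
    stop("format error in config ", path, ": line without '=': ",
         lines[bad][1], call. = FALSE)
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  stats::setNames(as.list(vals), keys)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  keys <- names(config)
  vals <- vapply(config, function(v) {
    if (is.numeric(v)) sprintf("%.15g", v) else as.character(v)
  }, character(1))
  writeLines(paste(keys, "=", vals), path)
  invisible(path)
}

fmt_events <- function(events) {
  if (length(events) == 0L) return("")
  paste(vapply(events, function(ev) sprintf("%.15g:%.15g", ev[1], ev[2]),
               character(1)), collapse = ";")
}

parse_events <- function(s) {
  s <- trimws(s)
  if (is.null(s) || !nzchar(s)) return(list())
  lapply(strsplit(s, ";", fixed = TRUE)[[1]], function(p)
    as.numeric(strsplit(p, ":", fixed = TRUE)[[1]]))
}

#' Convert between a scene and its flat configuration
#'
#' `scene_to_config()` flattens a [scene_config()] into the dotted-key form
#' used by the config files and manifests; `config_to_scene()` rebuilds the
#' scene, using [scene_config()] defaults for absent keys. The two are
#' mutually inverse on the represented fields.
#'
#' @param scene a [scene_config()].
#' @param config a named list as returned by [read_run_config()].
#' @param seed optional seed overriding `scene.seed` in the config.
#' @return `scene_to_config()`: a named list; `config_to_scene()`: a
#'   [scene_config()].
#' @export
scene_to_config <- function(scene) {
  det <- scene$detector; opt <- scene$optics; arena <- scene$arena
  list(
    "detector.width_px" = det$width_px,
    "detector.height_px" = det$height_px,
    "detector.bit_depth" = det$bit_depth,
    "detector.pixel_pitch_um" = det$pixel_pitch_um,
    "detector.sample_rate_hz" = det$sample_rate_hz,
    "detector.threshold" = det$threshold,
    "optics.focal_length_mm" = opt$focal_length_mm,
    "optics.filter_center_nm" = opt$filter_center_nm,
    "optics.filter_fwhm_nm" = opt$filter_fwhm_nm,
    "arena.side_length_m" = arena$side_length_m,
    "arena.height_m" = arena$height_m,
    "arena.detector_height_m" = arena$detector_height_m,
    "arena.assumed_distance_m" = arena$assumed_distance_m,
    "scene.tag_radius_m" = scene$tag_radius_m,
    "scene.tag_peak_intensity" = scene$tag_peak_intensity,
    "scene.reference_distance_m" = scene$reference_distance_m,
    "scene.background_mean" = scene$background_mean,
    "scene.background_sd" = scene$background_sd,
    "scene.n_hot_single" = scene$n_hot_single,
    "scene.n_hot_clusters" = scene$n_hot_clusters,
    "scene.n_dark" = scene$n_dark,
    "scene.speed_mean_mps" = scene$speed_mean_mps,
    "scene.speed_sd_mps" = scene$speed_sd_mps,
    "scene.turning_sd_rad" = scene$turning_sd_rad,
    "scene.roll_sd_rad" = scene$roll_sd_rad,
    "scene.roll_excursion_prob" = scene$roll_excursion_prob,
    "scene.occlusion_events" = fmt_events(scene$occlusion_events),
    "scene.perch_events" = fmt_events(scene$perch_events),
    "scene.duration_s" = scene$duration_s,
    "scene.seed" = scene$seed)
}

cfg_num <- function(config, key, default) {
  if (is.null(config[[key]])) default else as.numeric(config[[key]])
}

#' @rdname scene_to_config
#' @export
config_to_scene <- function(config, seed = NULL) {
  d <- scene_config()  # defaults
  det <- detector_config(
    width_px = cfg_num(config, "detector.width_px", d$detector$width_px),
    height_px = cfg_num(config, "detector.height_px", d$detector$height_px),
    bit_depth = cfg_num(config, "detector.bit_depth", d$detector$bit_depth),
    pixel_pitch_um = cfg_num(config, "detector.pixel_pitch_um",
                             d$detector$pixel_pitch_um),
    sample_rate_hz = cfg_num(config, "detector.sample_rate_hz",
                             d$detector$sample_rate_hz),
    threshold = cfg_num(config, "detector.threshold", d$detector$threshold))
  opt <- optics_config(
    focal_length_mm = cfg_num(config, "optics.focal_length_mm",
                              d$optics$focal_length_mm),
    filter_center_nm = cfg_num(config, "optics.filter_center_nm",
                               d$optics$filter_center_nm),
    filter_fwhm_nm = cfg_num(config, "optics.filter_fwhm_nm",
                             d$optics$filter_fwhm_nm))
  arena <- arena_config(
    side_length_m = cfg_num(config, "arena.side_length_m",
                            d$arena$side_length_m),
    height_m = cfg_num(config, "arena.height_m", d$arena$height_m),
    detector_height_m = cfg_num(config, "arena.detector_height_m",
                                d$arena$detector_height_m),
    assumed_distance_m = cfg_num(config, "arena.assumed_distance_m",
                                 d$arena$assumed_distance_m))
  scene_config(
    arena = arena, optics = opt, detector = det,
    tag_radius_m = cfg_num(config, "scene.tag_radius_m", d$tag_radius_m),
    tag_peak_intensity = cfg_num(config, "scene.tag_peak_intensity",
                                 d$tag_peak_intensity),
    reference_distance_m = cfg_num(config, "scene.reference_distance_m",
                                   arena$assumed_distance_m),
    background_mean = cfg_num(config, "scene.background_mean",
                              d$background_mean),
    background_sd = cfg_num(config, "scene.background_sd", d$background_sd),
    n_hot_single = cfg_num(config, "scene.n_hot_single", d$n_hot_single),
    n_hot_clusters = cfg_num(config, "scene.n_hot_clusters", d$n_hot_clusters),
    n_dark = cfg_num(config, "scene.n_dark", d$n_dark),
    speed_mean_mps = cfg_num(config, "scene.speed_mean_mps", d$speed_mean_mps),
    speed_sd_mps = cfg_num(config, "scene.speed_sd_mps", d$speed_sd_mps),
    turning_sd_rad = cfg_num(config, "scene.turning_sd_rad", d$turning_sd_rad),
    roll_sd_rad = cfg_num(config, "scene.roll_sd_rad", d$roll_sd_rad),
    roll_excursion_prob = cfg_num(config, "scene.roll_excursion_prob",
                                  d$roll_excursion_prob),
    occlusion_events = parse_events(config[["scene.occlusion_events"]]),
    perch_events = parse_events(config[["scene.perch_events"]]),
    duration_s = cfg_num(config, "scene.duration_s", d$duration_s),
    seed = if (!is.null(seed)) seed else cfg_num(config, "scene.seed", d$seed))
}

# manifest: the full flat config plus the package version, enough to
# reproduce the run exactly
write_manifest <- function(config, path) {
  config[["swirtrack.version"]] <-
    as.character(utils::packageVersion("swirtrack"))
  write_run_config(config, path)
}
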