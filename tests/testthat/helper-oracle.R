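# Independent brute-force detection oracle: materialise the whole frame,
# collect every unmasked pixel strictly above the threshold, return the last
# one in raster order (row-major), else the sentinel. Deliberately written
# with vectorised whole-image operations, the opposite of the streaming
# implementation it checks.
brute_detect <- function(frame, mask, threshold) {
  ok <- frame > threshold & !mask
  if (!any(ok)) return(c(row = 0L, col = 0L))
  idx <- which(t(ok))                  # raster-order linear indices
  last <- max(idx)
  nc <- ncol(frame)
  c(row = as.integer((last - 1L) %/% nc) + 1L,
    col = as.integer((last - 1L) %% nc) + 1L)
}

rand_frame <- function(h, w, grey_max = 255L) {
  matrix(sample.int(grey_max + 1L, h * w, replace = TRUE) - 1L, h, w)
}

rand_mask <- function(h, w, p = 0.05) {
  matrix(runif(h * w) < p, h, w)
}

# small, fast scene for end-to-end tests: study conditions except the sensor
# is a coarse 64 x 48 array (10x pitch, like 10x10 binning, so the field of
# view still covers most of the arena), the tag is scaled with the coarser
# sampling so its blob stays ~1 px wide as in the full-resolution geometry,
# and the run is short
tiny_scene <- function(..., width = 64L, height = 48L, duration_s = 0.25,
                       seed = 1L) {
  scene_config(
    detector = detector_config(width_px = width, height_px = height,
                               pixel_pitch_um = 250),
    tag_radius_m = 0.025,
    n_hot_single = 5L, n_hot_clusters = 1L,
    duration_s = duration_s, seed = seed, ...)
}
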