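test_that("trajectory is reproducible from the seed and stays in the arena", {
  scene <- tiny_scene(seed = 9)
  t1 <- simulate_trajectory(scene)
  t2 <- simulate_trajectory(scene)
  expect_identical(t1, t2)
  t3 <- simulate_trajectory(tiny_scene(seed = 10))
  expect_false(identical(t1$x_m, t3$x_m))

  half <- scene$arena$side_length_m / 2
  expect_true(all(abs(t1$x_m) <= half & abs(t1$y_m) <= half))
  expect_true(all(t1$z_m >= 6 & t1$z_m <= 8))
  expect_identical(nrow(t1), as.integer(round(0.25 * 102)))
})

test_that("degenerate flight models behave as stated", {
  still <- tiny_scene(seed = 2, speed_mean_mps = 0, speed_sd_mps = 0)
  tr <- simulate_trajectory(still)
  expect_true(all(tr$x_m == tr$x_m[1] & tr$y_m == tr$y_m[1] &
                  tr$z_m == tr$z_m[1]))

  straight <- scene_config(speed_sd_mps = 0, turning_sd_rad = 0,
                           roll_sd_rad = 0, roll_excursion_prob = 0,
                           duration_s = 0.1, seed = 3)
  tr2 <- simulate_trajectory(straight)
  step <- sqrt(diff(tr2$x_m)^2 + diff(tr2$y_m)^2 + diff(tr2$z_m)^2)
  # wall reflections preserve the step length
  expect_equal(step, rep(7.1 / 102, length(step)), tolerance = 1e-9)
})

test_that("occlusion, perching and roll govern visibility", {
  scene <- tiny_scene(seed = 4, duration_s = 1,
                      occlusion_events = list(c(0.2, 0.4)),
                      perch_events = list(c(0.6, 0.8)))
  tr <- simulate_trajectory(scene)
  occ <- tr$time_s >= 0.2 & tr$time_s <= 0.4
  perch <- tr$time_s >= 0.6 & tr$time_s <= 0.8
  expect_true(all(!tr$visible[occ]))
  expect_true(all(!tr$visible[perch]))
  # perched animals do not move
  expect_true(all(diff(tr$x_m[perch]) == 0))
  # elsewhere, visibility is exactly the roll criterion
  rest <- !occ & !perch
  expect_identical(tr$visible[rest], abs(tr$roll_rad[rest]) < pi / 2)
})

test_that("rendered frames are in range and hot pixels are fixed-pattern", {
  scene <- tiny_scene(seed = 5)
  hot <- simulate_hot_pixels(scene)
  expect_identical(dim(hot), c(48L, 64L))
  expect_gt(sum(hot), 0)
  tr <- simulate_trajectory(scene)
  set.seed(1)
  frames <- lapply(1:5, function(k) render_frame(tr[k, ], scene, hot))
  for (f in frames) {
    expect_identical(dim(f), c(48L, 64L))
    expect_true(all(f >= 0L & f <= 255L))
    expect_true(all(f[hot] == 255L))   # identical across all frames
  }
})

test_that("a face-on visible tag is detected near its projected position", {
  scene <- tiny_scene(seed = 6, background_sd = 0)
  point <- list(x_m = 0.1, y_m = -0.2, z_m = 7, roll_rad = 0, visible = TRUE)
  set.seed(2)
  f <- render_frame(point, scene, NULL)
  pos <- stream_detect(f, NULL, scene$detector)
  truth <- world_to_pixel(point$x_m, point$y_m, scene$optics, scene$detector,
                          point$z_m)
  sigma <- max(0.5, scene$tag_radius_m /
                 ground_sample_distance(250, 70, 7))
  tol <- ceiling(3 * sigma) + 1
  expect_lte(abs(pos[["row"]] - truth[["row"]]), tol)
  expect_lte(abs(pos[["col"]] - truth[["col"]]), tol)
})

test_that("a rolled-away tag leaves only background", {
  scene <- tiny_scene(seed = 6, background_sd = 0)
  point <- list(x_m = 0, y_m = 0, z_m = 7, roll_rad = pi / 2, visible = TRUE)
  set.seed(2)
  f <- render_frame(point, scene, NULL)
  expect_true(all(f == scene$background_mean))
  expect_true(is_sentinel(stream_detect(f, NULL, scene$detector)))
  # invisible tag, zero noise: every non-hot pixel equals the background mean
  point$roll_rad <- 0; point$visible <- FALSE
  hot <- simulate_hot_pixels(scene)
  f2 <- render_frame(point, scene, hot)
  expect_true(all(f2[!hot] == scene$background_mean))
})

test_that("blob intensity follows the inverse-square and foreshortening law", {
  scene <- tiny_scene(seed = 6, background_mean = 0, background_sd = 0)
  at <- function(z, roll) {
    # offset by half a pixel so the blob centre sits exactly on a pixel
    # centre (the array centre falls between pixels)
    off <- -0.5 * ground_sample_distance(250, 70, z)
    set.seed(3)
    max(render_frame(list(x_m = off, y_m = off, z_m = z, roll_rad = roll,
                          visible = TRUE), scene, NULL))
  }
  expect_identical(at(7, 0), 255L)                     # reference distance
  expect_identical(at(8, 0), as.integer(floor(255 * (7 / 8)^2 + 0.5)))
  expect_identical(at(7, pi / 3), as.integer(floor(255 * cos(pi / 3) + 0.5)))
})

test_that("render_sequence writes a complete, reproducible artifact set", {
  scene <- tiny_scene(seed = 8, duration_s = 0.1)
  d1 <- file.path(tempdir(), "seq1"); d2 <- file.path(tempdir(), "seq2")
  art1 <- render_sequence(scene, d1)
  art2 <- render_sequence(scene, d2)
  n <- as.integer(round(0.1 * 102))
  expect_length(art1$frame_paths, n)
  expect_length(art1$dark_paths, scene$n_dark)
  expect_identical(nrow(read_trajectory(art1$truth_path)), n)
  # byte-identical rerun from the same seed
  h1 <- vapply(art1$frame_paths, function(p) unname(tools::md5sum(p)), "")
  h2 <- vapply(art2$frame_paths, function(p) unname(tools::md5sum(p)), "")
  expect_identical(unname(h1), unname(h2))
  expect_identical(unname(tools::md5sum(art1$mask_path)),
                   unname(tools::md5sum(art2$mask_path)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("scene invariants are validated", {
  expect_error(scene_config(duration_s = 0), "invalid-config")
  expect_error(scene_config(tag_radius_m = 0), "invalid-config")
  expect_error(scene_config(occlusion_events = list(c(2, 1))),
               "invalid-config")
  scene <- tiny_scene()
  expect_error(render_frame(list(x_m = 5, y_m = 0, z_m = 7, roll_rad = 0,
                                 visible = TRUE), scene, NULL),
               "invalid-input")
})
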