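cfg <- detector_config()

det_df <- function(...) {
  m <- rbind(...)
  colnames(m) <- c("row", "col")
  m
}

test_that("last-known-position fill rule produces HELD waypoints", {
  tr <- track_stream(det_df(c(10, 10), c(0, 0), c(0, 0), c(12, 11)), cfg)
  expect_identical(tr$row, c(10L, 10L, 10L, 12L))
  expect_identical(tr$col, c(10L, 10L, 10L, 11L))
  expect_identical(tr$status, c("FIX", "HELD", "HELD", "FIX"))
})

test_that("sentinels before any detection give NO_FIX with no invented position", {
  tr <- track_stream(det_df(c(0, 0), c(0, 0)), cfg)
  expect_identical(tr$status, c("NO_FIX", "NO_FIX"))
  expect_identical(tr$row, c(0L, 0L))
  expect_true(all(is.na(tr$x_m)))
})

test_that("relative timestamps are linear from 0 to 1", {
  tr <- track_stream(det_df(c(1, 1), c(1, 2), c(1, 3), c(1, 4), c(1, 5)), cfg)
  expect_equal(tr$rel_time, c(0, 0.25, 0.5, 0.75, 1.0))
  expect_equal(track_stream(det_df(c(3, 3)), cfg)$rel_time, 0)
  empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  expect_identical(nrow(track_stream(empty, cfg)), 0L)
})

test_that("tracker invariants hold on random detection streams", {
  set.seed(11)
  for (k in 1:50) {
    n <- sample(1:60, 1)
    sentinel <- runif(n) < 0.4
    det <- cbind(row = ifelse(sentinel, 0L, sample(1:512, n, replace = TRUE)),
                 col = ifelse(sentinel, 0L, sample(1:640, n, replace = TRUE)))
    tr <- track_stream(det, cfg, optics = optics_config())
    # waypoint conservation
    expect_identical(nrow(tr), n)
    expect_identical(tr$frame_index, 0:(n - 1))
    # rel_time non-decreasing, 0 at start, 1 at end (when n > 1)
    expect_true(all(diff(tr$rel_time) >= 0))
    expect_equal(tr$rel_time[1], 0)
    if (n > 1) expect_equal(tr$rel_time[n], 1)
    # positions change only at FIX waypoints; no invented positions
    for (i in seq_len(n)) {
      if (tr$status[i] == "FIX") {
        expect_identical(c(tr$row[i], tr$col[i]),
                         unname(c(det[i, "row"], det[i, "col"])))
      } else if (tr$status[i] == "HELD") {
        expect_identical(c(tr$row[i], tr$col[i]),
                         c(tr$row[i - 1], tr$col[i - 1]))
        seen <- det[seq_len(i), , drop = FALSE]
        expect_true(any(seen[, "row"] == tr$row[i] &
                        seen[, "col"] == tr$col[i]))
      } else {
        expect_identical(c(tr$row[i], tr$col[i]), c(0L, 0L))
      }
    }
    # HELD implies the most recent FIX position
    expect_false(any(tr$status == "NO_FIX" & seq_len(n) >
                       match("FIX", tr$status, nomatch = n + 1L)))
  }
})

test_that("summary reports composition, duration and held gaps", {
  det <- det_df(c(5, 5), c(0, 0), c(0, 0), c(0, 0), c(6, 6), c(0, 0))
  tr <- track_stream(det, cfg)
  s <- summarize_track(tr)
  expect_identical(s$n_waypoints, 6L)
  expect_identical(s$n_fix, 2L)
  expect_identical(s$n_held, 4L)
  expect_identical(s$longest_held_frames, 3L)
  expect_equal(s$duration_s, 6 / 102)
  expect_equal(s$waypoints_per_s, 102)
  expect_error(summarize_track(tr[0, ]), "invalid-input")
})

test_that("a track of 164 s at 102 Hz reports ~102 waypoints per second", {
  n <- 164 * 102
  det <- cbind(row = rep(5L, n), col = rep(5L, n))
  s <- summarize_track(track_stream(det, cfg))
  expect_equal(s$duration_s, 164)
  expect_equal(s$n_waypoints / s$duration_s, 102)
})

test_that("constant position gives zero mean speed", {
  det <- cbind(row = rep(100L, 20), col = rep(200L, 20))
  s <- summarize_track(track_stream(det, cfg, optics = optics_config()))
  expect_equal(s$mean_speed_mps, 0)
})

test_that("mean FIX-to-FIX speed recovers a simulated straight flight at 7.1 m/s", {
  scene <- scene_config(speed_sd_mps = 0, turning_sd_rad = 0,
                        roll_sd_rad = 0, roll_excursion_prob = 0,
                        duration_s = 0.3, seed = 20)
  res <- track_scene(scene)
  # level flight at the assumed distance: pin z to 7 m by construction
  expect_true(all(abs(res$trajectory$z_m - 7) < 0.2))
  s <- summarize_track(res$track)
  expect_lt(abs(s$mean_speed_mps - 7.1) / 7.1, 0.05)
})

test_that("waypoint CSV round-trips including sentinels and empty world fields", {
  det <- det_df(c(0, 0), c(10, 10), c(0, 0), c(12, 11))
  tr <- track_stream(det, cfg, optics = optics_config())
  path <- tempfile(fileext = ".csv")
  write_waypoints(tr, path)
  header <- readLines(path, n = 1L)
  expect_identical(header, "frame_index,time_s,row,col,status,x_m,y_m,rel_time")
  back <- read_waypoints(path)
  expect_identical(back$row, tr$row)
  expect_identical(back$status, tr$status)
  expect_equal(back$x_m, tr$x_m, tolerance = 1e-12)
  expect_equal(back$rel_time, tr$rel_time)
  expect_equal(attr(back, "sample_rate_hz"), 102)
})
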