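cfg_small <- detector_config(width_px = 8L, height_px = 6L, threshold = 128L)

test_that("stream_detect returns the last supra-threshold pixel in raster order", {
  f <- matrix(0L, 6, 8)
  expect_identical(stream_detect(f, NULL, cfg_small, threshold = 0L),
                   c(row = 0L, col = 0L))

  f1 <- matrix(0L, 512, 640); f1[10, 20] <- 255L
  cfg_full <- detector_config()
  expect_identical(stream_detect(f1, NULL, cfg_full),
                   c(row = 10L, col = 20L))

  f2 <- matrix(0L, 512, 640)
  f2[3, 5] <- 200L; f2[3, 6] <- 200L; f2[7, 2] <- 200L
  expect_identical(stream_detect(f2, NULL, cfg_full),
                   c(row = 7L, col = 2L))
})

test_that("hot pixels are skipped during detection", {
  f <- matrix(0L, 6, 8); f[1, 1] <- 255L
  mask <- hot_mask(data.frame(row = 1, col = 1), cfg_small)
  expect_identical(stream_detect(f, mask, cfg_small, threshold = 100L),
                   c(row = 0L, col = 0L))
  # an unmasked detection is never a masked pixel
  f[1, 2] <- 255L
  pos <- stream_detect(f, mask, cfg_small, threshold = 100L)
  expect_false(mask[pos[["row"]], pos[["col"]]])
})

test_that("streaming detector matches the brute-force oracle on random frames", {
  set.seed(101)
  for (k in 1:500) {
    h <- sample(2:24, 1); w <- sample(2:32, 1)
    cfg <- detector_config(width_px = w, height_px = h,
                           threshold = sample(0:255, 1))
    f <- rand_frame(h, w)
    m <- rand_mask(h, w)
    expect_identical(stream_detect(f, m, cfg), brute_detect(f, m, cfg$threshold))
  }
})

test_that("sentinel is returned iff no unmasked pixel strictly exceeds T", {
  set.seed(7)
  for (k in 1:200) {
    h <- sample(2:12, 1); w <- sample(2:12, 1)
    cfg <- detector_config(width_px = w, height_px = h,
                           threshold = sample(0:255, 1))
    f <- rand_frame(h, w); m <- rand_mask(h, w, 0.2)
    pos <- stream_detect(f, m, cfg)
    expect_identical(is_sentinel(pos), !any(f > cfg$threshold & !m))
    # raising T never turns a sentinel into a detection
    if (is_sentinel(pos) && cfg$threshold < 255L)
      expect_true(is_sentinel(
        stream_detect(f, m, cfg, threshold = cfg$threshold + 1L)))
  }
})

test_that("comparison count equals width * height for every call", {
  set.seed(3)
  for (k in 1:20) {
    h <- sample(1:30, 1); w <- sample(1:30, 1)
    cfg <- detector_config(width_px = w, height_px = h, threshold = 128L)
    pos <- stream_detect(rand_frame(h, w), NULL, cfg, count = TRUE)
    expect_identical(attr(pos, "comparisons"), w * h)
  }
})

test_that("stream_detect validates frame, mask and threshold", {
  expect_error(stream_detect(matrix(0L, 5, 5), NULL, cfg_small),
               "invalid-input")
  expect_error(stream_detect(matrix(0L, 6, 8), matrix(FALSE, 2, 2), cfg_small),
               "invalid-input")
  expect_error(stream_detect(matrix(0L, 6, 8), NULL, cfg_small,
                             threshold = 300L), "invalid-config")
  expect_error(detector_config(threshold = -1), "invalid-config")
  expect_error(detector_config(width_px = 0), "invalid-config")
})

test_that("hot-pixel calibration applies the frequency rule", {
  mk <- function(v55) { f <- matrix(0L, 6, 8); f[5, 5] <- v55; f }
  dark <- replicate(10, mk(255L), simplify = FALSE)
  m <- calibrate_hot_pixels(dark, cfg_small, hot_threshold = 200L,
                            min_fraction = 0.5)
  expect_identical(mask_positions(m), data.frame(row = 5L, col = 5L))

  expect_identical(sum(calibrate_hot_pixels(
    replicate(10, matrix(0L, 6, 8), simplify = FALSE), cfg_small)), 0L)

  # hot in 6 of 10 frames: included at min_fraction 0.5, excluded at 0.7
  dark6 <- c(replicate(6, mk(255L), simplify = FALSE),
             replicate(4, mk(0L), simplify = FALSE))
  expect_true(calibrate_hot_pixels(dark6, cfg_small, 200L, 0.5)[5, 5])
  expect_false(calibrate_hot_pixels(dark6, cfg_small, 200L, 0.7)[5, 5])
})

test_that("calibration rejects empty or inconsistent input", {
  expect_error(calibrate_hot_pixels(list(), cfg_small), "invalid-input")
  expect_error(calibrate_hot_pixels(list(matrix(0L, 6, 8), matrix(0L, 3, 3)),
                                    cfg_small), "invalid-input")
})

test_that("latency and data-rate arithmetic matches the detector design", {
  lr <- latency_and_rates(detector_config())
  expect_identical(lr$raw_rate_Bps, 640 * 512 * 1 * 102)   # ~33.4 MB/s
  expect_identical(lr$output_rate_Bps, 4 * 102)            # ~0.4 kB/s
  expect_equal(lr$readout_period_s, 1 / 102)
  expect_equal(lr$worst_case_delay_s, lr$readout_period_s)
  expect_true(lr$worst_case_delay_s < 0.010)
  expect_equal(lr$readout_period_s * 102, 1)

  one <- latency_and_rates(
    detector_config(width_px = 1, height_px = 1, sample_rate_hz = 1),
    bytes_per_waypoint = 1)
  expect_identical(one$raw_rate_Bps, 1)
  expect_identical(one$output_rate_Bps, 1)
  expect_error(latency_and_rates(detector_config(), 0), "invalid-config")
})
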