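test_that("TIFF stacks round-trip bit-identically", {
  path <- withr::local_tempfile(fileext = ".tiff")
  const <- frame_sequence(array(7, dim = c(6, 5, 3)), fs = 25, bit_depth = 8L)
  write_frames(const, path)
  back <- read_frames(path, fs = 25)
  expect_equal(n_frames(back), 3L)
  expect_true(all(back$frames == 7))

  set.seed(11)
  clip <- frame_sequence(array(sample(0:4095, 8 * 9 * 4, replace = TRUE),
                               dim = c(8, 9, 4)),
                         fs = 25, bit_depth = 12L)
  write_frames(clip, path)
  expect_identical(read_frames(path)$frames, clip$frames)
})

test_that("raw + sidecar stacks round-trip with metadata", {
  path <- withr::local_tempfile(fileext = ".raw")
  set.seed(3)
  clip <- frame_sequence(array(sample(0:127, 5 * 4 * 6, replace = TRUE),
                               dim = c(5, 4, 6)),
                         fs = 30, timestamps = (0:5) / 30, bit_depth = 7L,
                         modality = "PPGI-NIR")
  write_frames(clip, path, format = "raw")
  back <- read_frames(path)
  expect_identical(back$frames, clip$frames)
  expect_equal(back$fs, 30)
  expect_equal(back$timestamps, clip$timestamps, tolerance = 1e-12)
  expect_identical(back$modality, "PPGI-NIR")
  expect_identical(back$bit_depth, 7L)
})

test_that("real-valued stacks round-trip through float TIFF with their scale", {
  path <- withr::local_tempfile(fileext = ".tiff")
  clip <- generate_scene(scene_config(rows = 10, cols = 12, duration = 0.6,
                                      seed = 4L))
  write_frames(clip, path)
  back <- read_frames(path)
  expect_equal(back$frames, clip$frames, tolerance = 1e-6)
  expect_equal(back$fs, 25)
})

test_that("a 10-s clip at 25 Hz has 250 frames", {
  seq <- generate_scene(scene_config(rows = 16, cols = 12, noise_sd = 0))
  expect_equal(n_frames(seq), 250L)
  expect_equal(clip_duration(seq), 10)
})

test_that("frame sequences validate their invariants", {
  expect_error(frame_sequence(list(matrix(0, 3, 3), matrix(0, 4, 3)), fs = 25),
               "identical dimensions")
  expect_error(frame_sequence(array(0, dim = c(3, 3, 2)), fs = 25,
                              timestamps = c(0.1, 0.1)),
               "strictly increasing")
  expect_error(read_frames(file.path(tempdir(), "nope.tiff")), "not found")
})

test_that("dropped-frame interpolation fills gaps linearly", {
  mk <- function(vals, ts) {
    frame_sequence(array(rep(vals, each = 4), dim = c(2, 2, length(vals))),
                   fs = 25, timestamps = ts)
  }
  # no gaps: identity
  seq0 <- mk(c(1, 2, 3), (0:2) / 25)
  expect_identical(interpolate_dropped_frames(seq0, 25)$frames, seq0$frames)

  # one missing frame between values 10 and 20 -> midpoint 15
  seq1 <- mk(c(10, 20), c(0, 2) / 25)
  out1 <- interpolate_dropped_frames(seq1, 25)
  expect_equal(n_frames(out1), 3L)
  expect_true(all(out1$frames[, , 2] == 15))

  # two missing frames between 0 and 30 -> linear interpolant 10, 20
  seq2 <- mk(c(0, 30), c(0, 3) / 25)
  out2 <- interpolate_dropped_frames(seq2, 25)
  expect_equal(as.vector(out2$frames[1, 1, ]), c(0, 10, 20, 30))

  # surviving frames are bit-identical, count matches round(span*fs)+1
  set.seed(5)
  vals <- runif(8)
  ts <- c(0:3, 5:6, 8:9) / 25  # gaps at slots 5 and 8
  seqg <- mk(vals, ts)
  outg <- interpolate_dropped_frames(seqg, 25)
  expect_equal(n_frames(outg), round((max(ts) - min(ts)) * 25) + 1)
  slots <- round((ts - ts[1]) * 25) + 1
  expect_identical(outg$frames[, , slots], seqg$frames)
})

test_that("interpolation preconditions and boundaries are enforced", {
  seq <- frame_sequence(array(0, dim = c(2, 2, 4)), fs = 25)
  expect_error(interpolate_dropped_frames(seq, 25), "timestamps")
  expect_error(interpolate_dropped_frames(seq, 25, drop_index = 1L),
               "boundary")
  out <- interpolate_dropped_frames(seq, 25, drop_index = 3L)
  expect_equal(n_frames(out), 5L)
})
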