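test_that("frame sequences round-trip through PNG directories", {
  set.seed(1)
  frames <- lapply(1:3, function(i) matrix(sample(0:255, 64 * 64, TRUE), 64, 64))
  fs <- frame_sequence(frames, fps = 10, modality = "nir")
  dir <- withr::local_tempdir()
  write_frame_sequence(fs, dir)
  back <- read_frame_sequence(dir, fps = 10, modality = "nir")
  expect_length(back$frames, 3)
  expect_equal(back$fps, 10)
  for (i in 1:3) expect_identical(back$frames[[i]], frames[[i]] * 1.0)

  fs20 <- frame_sequence(frames, fps = 20, modality = "rgb")
  expect_equal(fs20$fps, 20)
})

test_that("numeric file names order frames temporally, not lexicographically", {
  dir <- withr::local_tempdir()
  vals <- c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100, 110, 120)
  for (i in seq_along(vals)) {
    png::writePNG(matrix(vals[i] / 255, 8, 8),
                  file.path(dir, sprintf("frame_%d.png", i)))
  }
  fs <- read_frame_sequence(dir, fps = 10, modality = "nir")
  got <- vapply(fs$frames, function(f) f[1, 1], numeric(1))
  expect_equal(got, vals)  # frame_10 must follow frame_9, not frame_1
})

test_that("unreadable inputs raise informative errors", {
  expect_error(read_frame_sequence(tempfile("nodir"), 10, "nir"),
               class = "ovirr_input_error")
  empty <- withr::local_tempdir()
  expect_error(read_frame_sequence(empty, 10, "nir"), class = "ovirr_input_error")
  bad <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 8, 8), file.path(bad, "f_1.png"))
  png::writePNG(matrix(0.5, 9, 8), file.path(bad, "f_2.png"))
  expect_error(read_frame_sequence(bad, 10, "nir"), class = "ovirr_format_error")
  expect_error(frame_sequence(list(matrix(0, 4, 4)), fps = 10),
               class = "ovirr_format_error")
})

test_that("grayscale conversion of a constant RGB frame is constant (BT.601)", {
  fr <- array(100, dim = c(6, 8, 3))
  g <- as_gray(fr)
  expect_true(all(abs(g - 100) < 1e-9))
  # weights sum to 1 and favour green
  fr2 <- array(0, dim = c(2, 2, 3)); fr2[, , 2] <- 100
  expect_true(all(abs(as_gray(fr2) - 58.7) < 1e-9))
})

test_that("instance masks round-trip with sidecar metadata", {
  dir <- withr::local_tempdir()
  m1 <- matrix(0L, 16, 16); m1[4:12, 4:12] <- 1L
  m2 <- matrix(0L, 16, 16); m2[1:3, 1:3] <- 1L
  write_instance_mask(m1, file.path(dir, "mask_1.png"))
  write_instance_mask(m2, file.path(dir, "mask_2.png"))
  sidecar <- file.path(dir, "detections.csv")
  write.csv(data.frame(instance_id = c(1, 2), class_label = "thorax",
                       certainty = c(0.9, 0.5),
                       mask_file = c("mask_1.png", "mask_2.png")),
            sidecar, row.names = FALSE)
  masks <- read_instance_masks(dir, sidecar)
  expect_length(masks, 2)
  expect_equal(vapply(masks, `[[`, numeric(1), "certainty"), c(0.9, 0.5))
  expect_identical(masks[[1]]$mask, m1)
  # without sidecar: defaults
  masks2 <- read_instance_masks(file.path(dir, "mask_1.png"))
  expect_equal(masks2[[1]]$certainty, 1.0)
  expect_equal(masks2[[1]]$class_label, "thorax")
  # a 0.76-certainty detection survives the downstream 0.75 filter
  kept <- filter_detections(list(instance_mask(m1, certainty = 0.76)))
  expect_length(kept, 1)
})

test_that("RR series CSVs round-trip, including the empty series", {
  path <- withr::local_tempfile(fileext = ".csv")
  empty <- rr_series(numeric(0), numeric(0))
  write_rr_series(empty, path)
  expect_equal(readLines(path), "\"time_s\",\"rr_bpm\",\"rr_smoothed_bpm\"")
  s <- rr_series(times_s = c(10.0, 10.1, 10.2), rr_bpm = c(26.5, 27.0, 27.2),
                 rr_smoothed_bpm = c(26.8, 26.9, 27.0))
  write_rr_series(s, path)
  back <- read_rr_series(path)
  expect_equal(back$times_s, s$times_s, tolerance = 1e-9)
  expect_equal(back$rr_bpm, s$rr_bpm, tolerance = 1e-9)
  expect_equal(back$rr_smoothed_bpm, s$rr_smoothed_bpm, tolerance = 1e-9)
})

test_that("agreement tables reproduce their error statistics after re-reading", {
  tab <- rgb_validation_table()
  ag <- agreement(tab$rr_ref, tab$rr_video_total, video_id = tab$video_id)
  path <- withr::local_tempfile(fileext = ".csv")
  write_agreement_table(ag$records, path)
  back <- read.csv(path)
  expect_equal(mean(back$abs_err), 0.79, tolerance = 0.005)
  expect_equal(back$rr_ref, tab$rr_ref, tolerance = 1e-9)
})
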