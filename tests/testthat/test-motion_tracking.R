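test_that("FAST detection agrees with an exhaustive segment-test oracle", {
  # no contrast, no corners
  expect_equal(nrow(detect_feature_points(matrix(50, 20, 20))), 0)
  # a single bright pixel is the only corner
  img <- matrix(10, 20, 20)
  img[9, 12] <- 200
  pts <- detect_feature_points(img, cfg = tracker_config())
  expect_equal(nrow(pts), 1)
  expect_equal(c(pts$x, pts$y), c(12, 9))
  # full agreement with the per-pixel oracle on random images
  set.seed(12)
  for (i in 1:5) {
    rimg <- matrix(sample(0:40, 24 * 24, TRUE), 24, 24)
    got <- ovirr:::.fast_detect_cpp(rimg, 2)
    want <- fast_oracle(rimg, 2)
    got_set <- if (nrow(got)) paste(got$x, got$y) else character(0)
    want_set <- if (is.null(want)) character(0) else paste(want[, 1], want[, 2])
    expect_setequal(got_set, want_set)
  }
})

test_that("bucketing spreads points and the score cap is honoured", {
  sc <- std_scene()
  enhanced <- enhance(apply_mask(as_gray(sc$frames$frames[[1]]), sc$mask$mask))
  cfg <- tracker_config()
  pts <- detect_feature_points(enhanced, sc$mask, cfg)
  expect_lte(nrow(pts), cfg$max_points)
  expect_true(all(sc$mask$mask[cbind(pts$y, pts$x)] == 1))
  # at most one point per 4x4 cell
  cells <- paste((pts$x - 1) %/% 4, (pts$y - 1) %/% 4)
  expect_false(any(duplicated(cells)))
  # scores descending
  expect_true(all(diff(pts$score) <= 1e-9))
  # overriding max_points changes behaviour
  pts50 <- detect_feature_points(enhanced, sc$mask,
                                 tracker_config(max_points = 50))
  expect_equal(nrow(pts50), 50)
})

test_that("static scenes yield constant, fully valid trajectories", {
  img <- textured_image(40, 50)
  frames <- frame_sequence(rep(list(img), 5), fps = 10, modality = "nir")
  seeds <- data.frame(x = c(10, 25, 40), y = c(10, 20, 30))
  traj <- track(frames, seeds)
  expect_true(all(traj$valid))
  for (t in 1:5) {
    expect_equal(traj$positions[, t, 1], seeds$x, tolerance = 1e-6)
    expect_equal(traj$positions[, t, 2], seeds$y, tolerance = 1e-6)
  }
  # time reversal of a static sequence changes nothing
  rev_traj <- track(frame_sequence(rev(frames$frames), 10, "nir"), seeds)
  expect_equal(rev_traj$positions, traj$positions, tolerance = 1e-6)
})

test_that("a global 1 px/frame shift is recovered within 0.1 px", {
  big <- textured_image(60, 90)
  frames <- lapply(0:5, function(s) big[, (1 + s):(70 + s)])
  fs <- frame_sequence(frames, fps = 20, modality = "nir")
  seeds <- expand.grid(x = c(25, 35, 45), y = c(20, 30, 40))
  traj <- track(fs, seeds)
  expect_true(all(traj$valid))
  dx <- traj$positions[, -1, 1] - traj$positions[, -6, 1]
  dy <- traj$positions[, -1, 2] - traj$positions[, -6, 2]
  expect_true(all(abs(dx - (-1)) < 0.1))  # content moves left by 1 px/frame
  expect_true(all(abs(dy) < 0.1))
})

test_that("a subpixel sinusoidal shift is recovered with correlation > 0.99", {
  big <- textured_image(50, 80)
  n <- 60; fps <- 20
  shift <- 2 * sin(2 * pi * 0.5 * (0:(n - 1)) / fps)
  frames <- lapply(shift, function(s) {
    xs <- matrix(rep(seq_len(60) + 10 + s, each = 50), 50, 60)
    ys <- matrix(rep(seq_len(50), times = 60), 50, 60)
    matrix(ovirr:::bilinear_sample(big, ys, xs), 50, 60)
  })
  fs <- frame_sequence(frames, fps = fps, modality = "nir")
  traj <- track(fs, data.frame(x = c(30, 20), y = c(25, 35)))
  expect_true(all(traj$valid))
  xt <- traj$positions[1, , 1]
  expect_gt(abs(cor(xt, shift)), 0.99)
  expect_equal(diff(range(xt)), diff(range(shift)), tolerance = 0.2)
})

test_that("differentiation gives first differences of fully valid tracks", {
  img <- textured_image(30, 30)
  frames <- frame_sequence(rep(list(img), 4), fps = 10, modality = "nir")
  traj <- track(frames, data.frame(x = 15, y = 15))
  mo <- differentiate(traj)
  expect_equal(dim(mo$dx), c(1, 3))
  expect_true(all(abs(mo$dx) < 1e-6) && all(abs(mo$dy) < 1e-6))

  # analytic check on a hand-built trajectory set
  pos <- array(NA_real_, c(2, 5, 2))
  pos[1, , 1] <- 3 * (0:4); pos[1, , 2] <- 7
  pos[2, , 1] <- sin(2 * pi * 0.2 * (0:4)); pos[2, , 2] <- 0:4
  traj2 <- structure(list(positions = pos,
                          valid = matrix(TRUE, 2, 5), fps = 10),
                     class = "trajectory_set")
  mo2 <- differentiate(traj2)
  expect_equal(mo2$dx[1, ], rep(3, 4))
  expect_equal(mo2$dy[2, ], rep(1, 4))
  # constant offsets vanish under differencing
  traj3 <- traj2; traj3$positions <- traj3$positions + 5
  expect_equal(differentiate(traj3)$dx, mo2$dx)

  # losing every trajectory is an error
  traj4 <- traj2; traj4$valid[, 5] <- FALSE
  expect_error(differentiate(traj4), class = "ovirr_degenerate_input")
})

test_that("the sinusoidal derivative has its spectral peak at the drive frequency", {
  fps <- 10; n <- 100; f <- 0.4
  x <- sin(2 * pi * f * (0:(n - 1)) / fps)
  d <- diff(x)
  mags <- vapply(1:45, function(k) dft_bin_mag(d, k), numeric(1))
  k_peak <- which.max(mags)
  expect_equal(k_peak * fps / length(d), f, tolerance = fps / length(d))
})

test_that("most seeded points survive a 30 s synthetic clip", {
  run <- std_run()
  entries <- run$log$entries
  seeded <- Filter(function(e) e$stage == "detect", entries)[[1]]$points_seeded
  surviving <- Filter(function(e) e$stage == "track", entries)[[1]]$points_surviving
  expect_gte(surviving / seeded, 0.8)
})
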