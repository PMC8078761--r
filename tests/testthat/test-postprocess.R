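# Image-error scoring, thresholding, segment building, head-tail
# orientation, gap interpolation and smoothing.

test_that("image error separates faithful, inverted and noise images", {
  fix <- get_fix()
  r <- fix$refs[[1]]
  ang <- unwrap_body(skeleton_to_angles(r$skeleton))
  self <- image_error(r$processed, ang, r)
  expect_lte(self$error, 0.1)
  expect_true(self$error >= 0 && self$error <= 1)
  # intensity-inverted original: perfect anti-correlation is still a match
  inv <- r$processed; inv$image <- 1 - inv$image
  expect_equal(image_error(inv, ang, r)$error, self$error,
               tolerance = 1e-9)
  # independent noise frames score close to 1 and over the 0.3 threshold
  set.seed(33)
  errs <- vapply(1:5, function(i) {
    noise <- r$processed
    noise$image <- matrix(runif(48 * 48), 48, 48)
    image_error(noise, ang, r)$error
  }, numeric(1))
  expect_true(all(errs > 0.3))
  expect_gt(mean(errs), 0.6)
})

test_that("image error is invariant to translating the worm", {
  fix <- get_fix()
  r <- fix$refs[[1]]
  ang <- unwrap_body(skeleton_to_angles(r$skeleton))
  base <- image_error(r$processed, ang, r)
  shifted <- r$processed
  shifted$image <- matrix(r$processed$background_value, 48, 48)
  shifted$image[4:48, 4:48] <- r$processed$image[1:45, 1:45]
  moved <- image_error(shifted, ang, r)
  expect_equal(moved$error, base$error, tolerance = 0.02)
  expect_equal(unname(moved$offset - base$offset), c(3, 3))
})

test_that("threshold selection reports the labeled-frame distribution", {
  expect_warning(thr <- choose_threshold(numeric(0)), "default")
  expect_equal(thr$threshold, 0.3)
  errs <- c(0.02, 0.05, 0.08, 0.11, 0.14)
  thr2 <- choose_threshold(errs)
  expect_equal(thr2$retained_fraction, 1)  # all below 0.3
  # retained fraction is monotone in the threshold
  fr <- vapply(c(0.05, 0.1, 0.2, 0.3), function(t)
    choose_threshold(errs, threshold = t)$retained_fraction, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("constant-pose sequences form a single segment", {
  th <- runif(30, -pi, pi)
  pairs <- lapply(1:50, function(i)
    list(theta = th, theta_flipped = flip_centerline(th), frame_index = i))
  segs <- build_segments(pairs, fps = 30, seed = 1)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$frames, 1:50)
  # chosen orientations are mutually consistent
  d <- apply(segs[[1]]$angles, 1, mean_abs_angle_distance, c2 = segs[[1]]$angles[1, ])
  expect_true(all(d < 1e-9))
})

test_that("corrupted frames become gaps inside a single segment", {
  set.seed(34)
  th <- runif(40, -pi, pi)
  pairs <- lapply(1:60, function(i)
    list(theta = th, theta_flipped = flip_centerline(th), frame_index = i))
  bad <- runif(40, -pi, pi)  # far from th in both orientations
  stopifnot(mean_abs_angle_distance(th, bad) > 30 * pi / 180)
  pairs[[30]] <- list(theta = bad, theta_flipped = flip_centerline(bad),
                      frame_index = 30)
  segs <- build_segments(pairs, fps = 30, seed = 1)
  expect_length(segs, 1)
  expect_false(30 %in% segs[[1]]$frames)
  expect_true(all(c(29, 31) %in% segs[[1]]$frames))
})

test_that("alternating flips are unified within a segment", {
  th <- seq(-1, 1, length.out = 30)  # asymmetric pose
  pairs <- lapply(1:40, function(i) {
    t2 <- if (i %% 2) th else flip_centerline(th)
    list(theta = t2, theta_flipped = flip_centerline(t2), frame_index = i)
  })
  segs <- build_segments(pairs, fps = 30, seed = 1)
  expect_length(segs, 1)
  d <- apply(segs[[1]]$angles, 1, mean_abs_angle_distance,
             c2 = segs[[1]]$angles[1, ])
  expect_true(all(d < 30 * pi / 180))
})

test_that("short segments are discarded", {
  th <- runif(20, -pi, pi)
  other <- th + 2  # far from th
  mk <- function(t, i) list(theta = t, theta_flipped = flip_centerline(t),
                            frame_index = i)
  pairs <- c(lapply(1:3, function(i) mk(th, i)),        # 3 frames = 0.1 s
             lapply(4:23, function(i) mk(other, i)))    # 20 frames
  segs <- build_segments(pairs, fps = 30, seed = 1)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$frames, 4:23)
})

test_that("segments orient by labels and propagate to neighbors", {
  fix <- get_fix()
  truth <- fix$video$truth
  pairs <- simulate_predictions(truth, sd = 0.02, seed = 3)
  segs <- build_segments(pairs, fix$video$fps, seed = 2)
  lab <- which(fix$video$labeled)
  oriented <- orient_segments(segs, lab, truth[lab, , drop = FALSE])
  for (s in oriented) {
    expect_true(s$orientation_source %in% c("labels", "neighbor"))
    for (j in seq_along(s$frames)) {
      tr <- truth[s$frames[j], ]
      expect_lte(rmse_angle_distance(s$angles[j, ], tr),
                 rmse_angle_distance(s$angles[j, ], flip_centerline(tr)))
    }
  }
  # orientation is a pure relabeling: the unordered point set per frame is
  # unchanged
  s1 <- oriented[[1]]
  j <- 1
  pts <- angles_to_skeleton(s1$angles[j, ], dS = 1)
  pair <- pairs[[s1$frames[j]]]
  pts_a <- angles_to_skeleton(pair$theta, dS = 1)
  pts_b <- angles_to_skeleton(pair$theta_flipped, dS = 1)
  ok_a <- max(abs(sweep(pts, 2, pts[1, ]) - sweep(pts_a, 2, pts_a[1, ]))) < 1e-6
  rev_b <- pts_b[rev(seq_len(nrow(pts_b))), ]
  ok_b <- max(abs(sweep(pts, 2, pts[1, ]) - sweep(rev_b, 2, rev_b[1, ]))) < 1e-6
  expect_true(ok_a || ok_b)
})

test_that("a globally flipped segment is flipped exactly once by labels", {
  fix <- get_fix()
  truth <- fix$video$truth[1:60, ]
  # force every prediction into the flipped orientation
  pairs <- lapply(seq_len(nrow(truth)), function(i) {
    t2 <- flip_centerline(truth[i, ])
    list(theta = t2, theta_flipped = flip_centerline(t2), frame_index = i)
  })
  segs <- build_segments(pairs, fix$video$fps, seed = 40)
  lab <- which(fix$video$labeled[1:60])
  oriented <- orient_segments(segs, lab, fix$video$truth[lab, , drop = FALSE])
  s <- oriented[[1]]
  for (j in seq_along(s$frames)) {
    tr <- truth[s$frames[j], ]
    expect_lt(rmse_angle_distance(s$angles[j, ], tr), 1e-9)
  }
})

test_that("gap interpolation fills small gaps exactly on cubic motion", {
  t <- 1:40
  series <- outer(t, c(1, 2), function(tt, j)
    0.001 * tt^3 - 0.02 * tt^2 + 0.3 * tt + j)
  holed <- series
  holed[18:19, ] <- NA
  filled <- interpolate_gaps(holed, max_gap = 4)
  expect_equal(filled[18:19, ], series[18:19, ], tolerance = 1e-6)
  # no gaps: identity
  expect_identical(interpolate_gaps(series), series)
  # 5-frame gaps stay open
  holed5 <- series; holed5[10:14, ] <- NA
  expect_true(all(is.na(interpolate_gaps(holed5, max_gap = 4)[10:14, ])))
})

test_that("Savitzky-Golay smoothing preserves cubics and reduces noise", {
  t <- 1:60
  cubic <- matrix(0.002 * t^3 - 0.05 * t^2 + t, ncol = 1)
  sm <- smooth_angles(cubic)
  expect_equal(sm[5:56], cubic[5:56], tolerance = 1e-6)
  const <- matrix(0.7, 60, 2)
  expect_equal(smooth_angles(const), const, tolerance = 1e-9)
  set.seed(35)
  noise <- matrix(rnorm(300), 300, 1)
  expect_lt(var(smooth_angles(noise)[, 1]), var(noise[, 1]))
  short <- matrix(rnorm(10), 5, 2)
  expect_warning(out <- smooth_angles(short), "shorter")
  expect_identical(out, short)
})
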