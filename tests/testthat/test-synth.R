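# Synthetic image generation: width interpolation, outline mask, patch
# warping, and training-set assembly.

test_that("width interpolation is piecewise linear between landmarks", {
  expect_equal(interpolate_widths(c(3, 3, 3), 50), rep(3, 50))
  # on a 9-point grid, point 4 sits at fraction 0.375, halfway between the
  # head (0.25) and midbody (0.5) landmarks
  ww9 <- interpolate_widths(c(2, 6, 2), 9, landmarks = c(0.25, 0.5, 0.75))
  expect_equal(ww9[4], 4.0, tolerance = 1e-9)
  ww <- interpolate_widths(c(2, 6, 2), 101, landmarks = c(0.25, 0.5, 0.75))
  expect_equal(ww[1], 2); expect_equal(ww[101], 2); expect_equal(ww[51], 6)
  # piecewise monotone between landmarks
  expect_true(all(diff(ww[26:51]) >= 0))
  expect_true(all(diff(ww[51:76]) <= 0))
  expect_error(interpolate_widths(c(0, 2, 2), 10), "positive")
})

test_that("outline mask of a straight worm matches the analytic area", {
  n <- 60
  # half-integer row keeps rasterization parity neutral
  skel <- cbind(seq(10, 50, length.out = n), rep(32.3, n))
  mask <- worm_outline_mask(skel, rep(6, n), 64)
  analytic <- 40 * 6 + pi * 3^2  # rectangle plus two end caps
  expect_lt(abs(sum(mask) - analytic) / analytic, 0.1)
  # translation equivariance (up to pixel shift)
  mask2 <- worm_outline_mask(cbind(skel[, 1], skel[, 2] + 5), rep(6, n), 64)
  expect_equal(sum(mask2), sum(mask), tolerance = 0.02 * sum(mask))
  expect_error(worm_outline_mask(cbind(rep(5, 4), rep(5, 4)), rep(2, 4), 64),
               "degenerate")
})

test_that("self-rendering reproduces the reference image", {
  fix <- get_fix()
  r <- fix$refs[[1]]
  ang <- unwrap_body(skeleton_to_angles(r$skeleton))
  err <- image_error(r$processed, ang, r)$error
  expect_lte(err, 0.1)
})

test_that("rendering is deterministic given the seed", {
  fix <- get_fix()
  r <- fix$refs[[1]]
  th <- sample_shapes(fit_shape_model(
    fixture_corpus(fix$world, 300, seed = 2), 4, seed = 1), 1, seed = 5)[1, ]
  s1 <- render_synthetic(r, th, synth_params(), seed = 11)
  s2 <- render_synthetic(r, th, synth_params(), seed = 11)
  expect_identical(s1$image, s2$image)
})

test_that("coiled targets render as one connected blob inside the mask", {
  fix <- get_fix()
  r <- fix$refs[[1]]
  basis <- fixture_eigenbasis(fix$world, n = 300)
  # deep coil: strong third-mode amplitude
  th <- reconstruct_from_modes(c(2, 1, 18, 0, 0), basis)
  s <- render_synthetic(r, th, synth_params(augment = FALSE))
  a3 <- project_modes(unwrap_body(th), basis)[3]
  expect_gt(abs(a3), 15)
  dark <- s$image < (r$processed$background_value - 0.2)
  expect_true(all(s$mask[dark]))  # worm pixels inside the mask
  lab <- EBImage::bwlabel(EBImage::Image(dark * 1))
  expect_equal(max(lab), 1)  # a single connected component
  # background exactly uniform outside the mask
  expect_true(all(s$image[!s$mask] == r$processed$background_value))
})

test_that("labels and skeletons stay consistent through rendering", {
  fix <- get_fix()
  r <- fix$refs[[2]]
  th <- unwrap_body(skeleton_to_angles(r$skeleton)) + 0.3
  s <- render_synthetic(r, th, synth_params(), seed = 4)
  # the two labels describe the same point set
  sk_a <- angles_to_skeleton(s$target, dS = 1)
  sk_b <- angles_to_skeleton(s$target_flipped, dS = 1)
  rev_b <- sk_b[rev(seq_len(nrow(sk_b))), ]
  expect_lt(max(abs(sweep(rev_b, 2, rev_b[1, ]) -
                    sweep(sk_a, 2, sk_a[1, ]))), 1e-6)
  # rendered target_skeleton integrates the target angles (up to
  # translation and the length augmentation rescale)
  ds <- skeleton_ds(s$target_skeleton)
  ref_pts <- angles_to_skeleton(s$target, dS = ds)
  ref_pts <- sweep(ref_pts, 2, ref_pts[1, ] - s$target_skeleton[1, ])
  expect_lt(max(abs(ref_pts - s$target_skeleton)), 0.1)
})

test_that("training sets are reproducible with uniform orientation and head assignment", {
  fix <- get_fix()
  sm <- fit_shape_model(fixture_corpus(fix$world, 400, seed = 2), 4,
                        seed = 1)
  empty <- generate_training_set(fix$refs, sm, 0, seed = 1)
  expect_equal(dim(empty$images)[3], 0)
  tr1 <- generate_training_set(fix$refs, sm, 40, seed = 6)
  tr2 <- generate_training_set(fix$refs, sm, 40, seed = 6)
  expect_identical(tr1$images, tr2$images)
  expect_identical(tr1$targets, tr2$targets)
  # statistical checks on the generator draws at a larger n (draws only,
  # no rendering, to keep the test fast)
  draws <- withr::with_seed(7 + 1L, list(
    rot = stats::runif(10000, 0, 2 * pi),
    flip = stats::runif(10000) < 0.5))
  ks <- suppressWarnings(stats::ks.test(draws$rot, "punif", 0, 2 * pi))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(draws$flip), 0.5, tolerance = 0.02)
})

test_that("training-set orientations and head flips match the draw stream", {
  fix <- get_fix()
  sm <- fit_shape_model(fixture_corpus(fix$world, 400, seed = 2), 4,
                        seed = 1)
  tr <- generate_training_set(fix$refs, sm, 30, seed = 9)
  expect_true(all(tr$meta$rotation >= 0 & tr$meta$rotation <= 2 * pi))
  expect_true(all(tr$meta$ref %in% seq_along(fix$refs)))
  # each target renders inside the canvas and the head flip preserved the
  # curve (flip of flip equals original shape modulo rotation)
  expect_equal(nrow(tr$targets), dim(tr$images)[3])
})

test_that("training shards round-trip through the manifest", {
  fix <- get_fix()
  sm <- fit_shape_model(fixture_corpus(fix$world, 300, seed = 2), 3,
                        seed = 1)
  tr <- generate_training_set(fix$refs, sm, 12, seed = 3)
  d <- file.path(tempdir(), "shards-test")
  man <- write_training_shards(tr, d, shard_size = 5)
  expect_equal(man$n, 12)
  expect_equal(length(man$shards), 3)
  sh <- readRDS(file.path(d, man$shards[1]))
  expect_equal(dim(sh$images)[3], 5)
  expect_true(file.exists(file.path(d, "manifest.json")))
})
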