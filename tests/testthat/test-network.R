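# Network construction, the symmetric loss, training behavior and
# prediction contracts.

test_that("symmetric loss has the head-tail equivalences", {
  set.seed(31)
  th <- runif(50, -pi, pi)
  a <- runif(50, -pi, pi)
  expect_equal(symmetric_loss(th, th), 0)
  expect_equal(symmetric_loss(flip_centerline(a), a), 0, tolerance = 1e-12)
  # brute-force the two branch distances
  expect_equal(symmetric_loss(th, a),
               min(rmse_angle_distance(th, a),
                   rmse_angle_distance(th, flip_centerline(a))))
  # invariance to flipping either argument (to rounding of the wrap)
  expect_lt(abs(symmetric_loss(th, a) -
                symmetric_loss(th, flip_centerline(a))), 1e-12)
  expect_lt(abs(symmetric_loss(flip_centerline(th), a) -
                symmetric_loss(th, a)), 1e-12)
  expect_error(symmetric_loss(th, a[-1]), "length")
})

test_that("network builds with the contracted output shape", {
  spec <- network_spec(input_side = 48, stage_filters = c(8, 16, 32),
                       blocks_per_stage = 1)
  net <- build_pose_network(spec, seed = 1)
  imgs <- array(runif(48 * 48 * 4), c(48, 48, 4))
  preds <- predict_centerlines(net, imgs)
  expect_length(preds, 4)
  expect_length(preds[[1]]$theta, 100)
  expect_equal(preds[[1]]$theta_flipped,
               flip_centerline(preds[[1]]$theta))
  # the 32-px minimum size builds and runs
  net32 <- build_pose_network(network_spec(input_side = 32,
                                           stage_filters = c(8, 16, 32),
                                           blocks_per_stage = 1), seed = 1)
  p32 <- predict_centerlines(net32, array(runif(32 * 32), c(32, 32, 1)))
  expect_length(p32[[1]]$theta, 100)
})

test_that("initialization is deterministic given the seed", {
  spec <- network_spec(input_side = 32, stage_filters = c(8, 16, 32),
                       blocks_per_stage = 1)
  imgs <- array(runif(32 * 32 * 2), c(32, 32, 2))
  p1 <- predict_centerlines(build_pose_network(spec, seed = 5), imgs)
  p2 <- predict_centerlines(build_pose_network(spec, seed = 5), imgs)
  expect_identical(p1[[1]]$theta, p2[[1]]$theta)
  p3 <- predict_centerlines(build_pose_network(spec, seed = 6), imgs)
  expect_false(identical(p1[[1]]$theta, p3[[1]]$theta))
})

test_that("the network overfits a tiny batch", {
  fix <- get_fix()
  sm <- fit_shape_model(fixture_corpus(fix$world, 400, seed = 2), 4,
                        seed = 1)
  tr <- generate_training_set(fix$refs, sm, 32, seed = 13)
  spec <- network_spec(input_side = 48, stage_filters = c(8, 16, 32),
                       blocks_per_stage = 1)
  net <- build_pose_network(spec, seed = 1)
  cfg <- train_config(batch = 32, epochs = 200, lr = 0.01, seed = 1)
  net <- train_pose_network(net, tr$images, tr$targets,
                            tr$images[, , 1:8], tr$targets[1:8, ], cfg)
  expect_lt(net$history$train_loss[200], 0.1)
  # history and checkpoint-policy contracts
  expect_equal(nrow(net$history), 200)
  expect_lte(min(net$history$eval_loss),
             net$history$eval_loss[200])
})

test_that("batch and single-frame prediction agree", {
  spec <- network_spec(input_side = 32, stage_filters = c(8, 16, 32),
                       blocks_per_stage = 1)
  net <- build_pose_network(spec, seed = 2)
  imgs <- array(runif(32 * 32 * 3), c(32, 32, 3))
  pb <- predict_centerlines(net, imgs)
  ps <- predict_centerlines(net, imgs[, , 2, drop = FALSE])
  expect_equal(pb[[2]]$theta, ps[[1]]$theta, tolerance = 1e-5)
  # duplicated frames give identical pairs
  dup <- array(imgs[, , c(1, 1)], c(32, 32, 2))
  pd <- predict_centerlines(net, dup)
  expect_identical(pd[[1]]$theta, pd[[2]]$theta)
})

test_that("mismatched frame sizes are resized with a warning", {
  spec <- network_spec(input_side = 32, stage_filters = c(8, 16, 32),
                       blocks_per_stage = 1)
  net <- build_pose_network(spec, seed = 2)
  expect_warning(p <- predict_centerlines(net, array(runif(48 * 48),
                                                     c(48, 48, 1))),
                 "resizing")
  expect_length(p[[1]]$theta, 100)
})

test_that("networks checkpoint and reload exactly", {
  spec <- network_spec(input_side = 32, stage_filters = c(8, 16, 32),
                       blocks_per_stage = 1)
  net <- build_pose_network(spec, seed = 3)
  f <- tempfile(fileext = ".rds")
  save_pose_network(net, f)
  back <- load_pose_network(f)
  imgs <- array(runif(32 * 32), c(32, 32, 1))
  expect_identical(predict_centerlines(net, imgs)[[1]]$theta,
                   predict_centerlines(back, imgs)[[1]]$theta)
})
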