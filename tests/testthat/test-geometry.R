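# Angle/skeleton conversions, angular metrics, head-tail flip and the
# eigenworm projection machinery.

test_that("angles_to_skeleton integrates tangent angles", {
  expect_equal(angles_to_skeleton(c(0, 0, 0), dS = 1),
               cbind(x = 0:3, y = rep(0, 4)))
  expect_equal(angles_to_skeleton(c(pi / 2, pi / 2), dS = 2),
               cbind(x = rep(0, 3), y = c(0, 2, 4)),
               tolerance = 1e-12)
  # cumulative-sum oracle on random angles
  set.seed(42)
  th <- runif(10, -pi, pi)
  pts <- angles_to_skeleton(th, dS = 1.7, origin = c(2, -1))
  oracle <- cbind(2 + cumsum(c(0, 1.7 * cos(th))),
                  -1 + cumsum(c(0, 1.7 * sin(th))))
  expect_equal(unname(pts), oracle)
  expect_error(angles_to_skeleton(th, dS = 0), "positive")
})

test_that("skeleton_to_angles inverts the integration", {
  set.seed(7)
  th <- runif(25, -pi, pi)
  sk <- angles_to_skeleton(th, dS = 1)
  expect_lt(max(abs(wrap_angle_diff(skeleton_to_angles(sk), th))), 1e-9)
  # collinear points all give the same angle
  pts <- cbind(c(0, 1, 2), c(0, 1, 2))
  expect_equal(skeleton_to_angles(pts), rep(pi / 4, 2))
  # circle arc: angles equal the analytic tangent directions
  tt <- seq(0, pi / 2, length.out = 50)
  arc <- cbind(cos(tt), sin(tt))
  ang <- skeleton_to_angles(arc)
  mid <- (tt[-1] + tt[-length(tt)]) / 2
  expect_lt(max(abs(wrap_angle_diff(ang, mid + pi / 2))), 1e-6)
  expect_error(skeleton_to_angles(cbind(0, 0)), "at least 3")
  expect_error(skeleton_to_angles(cbind(c(0, 0, 1), c(0, 0, 1))),
               "duplicate")
})

test_that("wrap_angle_diff maps to the principal interval", {
  expect_equal(wrap_angle_diff(1.3, 1.3), 0)
  expect_equal(wrap_angle_diff(pi, -pi), 0)
  expect_equal(wrap_angle_diff(0.1, 6.2), 0.1 - 6.2 + 2 * pi,
               tolerance = 1e-12)
  set.seed(1)
  a <- runif(1000, -20, 20); b <- runif(1000, -20, 20)
  d <- wrap_angle_diff(a, b)
  expect_true(all(d > -pi & d <= pi))
  expect_equal(d, -wrap_angle_diff(b, a), tolerance = 1e-12)
  expect_equal(sin(d), sin(a - b), tolerance = 1e-12)
})

test_that("angular metrics match brute-force oracles", {
  set.seed(11)
  th1 <- runif(100, -pi, pi); th2 <- runif(100, -pi, pi)
  eps <- atan2(sin(th1 - th2), cos(th1 - th2))
  expect_equal(rmse_angle_distance(th1, th2), sqrt(mean(eps^2)))
  expect_equal(mean_abs_angle_distance(th1, th2), mean(abs(eps)))
  expect_equal(rmse_angle_distance(th1, th1), 0)
  expect_equal(rmse_angle_distance(th1, th1 + pi), pi)
  expect_equal(mean_abs_angle_distance(th1 + 0.4, th1), 0.4,
               tolerance = 1e-12)
  expect_error(rmse_angle_distance(th1, th2[-1]), "length")
})

test_that("rmse distance is a pseudometric and flip-invariant", {
  set.seed(5)
  for (i in 1:20) {
    a <- runif(30, -pi, pi); b <- runif(30, -pi, pi)
    cc <- runif(30, -pi, pi)
    expect_equal(rmse_angle_distance(a, b), rmse_angle_distance(b, a))
    expect_lte(rmse_angle_distance(a, cc),
               rmse_angle_distance(a, b) + rmse_angle_distance(b, cc) + 1e-12)
    expect_equal(rmse_angle_distance(flip_centerline(a), flip_centerline(b)),
                 rmse_angle_distance(a, b), tolerance = 1e-12)
  }
})

test_that("flip_centerline is an involution traversing the same curve", {
  set.seed(9)
  th <- runif(40, -pi, pi)
  expect_equal(flip_centerline(flip_centerline(th)), wrap_angles(th),
               tolerance = 1e-12)
  expect_equal(flip_centerline(c(0, 0)), c(pi, pi))
  # flipped skeleton equals the reversed point list up to translation
  sk <- angles_to_skeleton(th, dS = 1)
  skf <- angles_to_skeleton(flip_centerline(th), dS = 1)
  rev_sk <- sk[rev(seq_len(nrow(sk))), ]
  shift <- skf[1, ] - rev_sk[1, ]
  expect_lt(max(abs(sweep(rev_sk, 2, -shift) - skf)), 1e-9)
})

test_that("unwrap_body restores continuity without moving the curve", {
  th <- seq(-4.5, 4.5, length.out = 80)  # winds beyond (-pi, pi]
  wrapped <- wrap_angles(th)
  out <- unwrap_body(wrapped)
  # continuity restored up to one global 2*pi offset
  expect_equal(diff(out), diff(th), tolerance = 1e-9)
  expect_equal(wrap_angles(out - th), rep(0, 80), tolerance = 1e-9)
  expect_equal(angles_to_skeleton(unwrap_body(wrapped)),
               angles_to_skeleton(wrapped), tolerance = 1e-9)
})

test_that("eigenbasis recovers planted structure", {
  N <- 40
  v1 <- sin(2 * pi * seq_len(N) / N); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- cos(2 * pi * seq_len(N) / N); v2 <- v2 / sqrt(sum(v2^2))
  set.seed(3)
  A <- cbind(rnorm(300, sd = 3), rnorm(300, sd = 2))
  shapes <- A %*% rbind(v1, v2) + matrix(rnorm(300 * N, sd = 0.01), 300)
  basis <- compute_eigenbasis(shapes, d = 2)
  # the first two components span {v1, v2}: projections onto the span
  # reconstruct both vectors
  P <- basis$components %*% t(basis$components)
  expect_lt(max(abs(P %*% v1 - v1)), 1e-3)
  expect_lt(max(abs(P %*% v2 - v2)), 1e-3)
  expect_equal(unname(crossprod(basis$components)), diag(2),
               tolerance = 1e-8)
  expect_lte(sum(basis$var_explained), 1)
  # constant library: mean recovered, projections zero
  same <- matrix(rep(shapes[1, ], 10), 10, byrow = TRUE)
  b2 <- compute_eigenbasis(same, d = 1)
  expect_equal(b2$mean, shapes[1, ], tolerance = 1e-12)
  expect_equal(as.numeric(project_modes(shapes[1, ], b2)), 0,
               tolerance = 1e-8)
})

test_that("project_modes is the orthogonal projection", {
  fix <- get_fix()
  basis <- fixture_eigenbasis(fix$world, n = 300)
  expect_equal(project_modes(basis$mean, basis), rep(0, 5),
               tolerance = 1e-9)
  c2 <- basis$mean + 3 * basis$components[, 2]
  expect_equal(project_modes(c2, basis), c(0, 3, 0, 0, 0),
               tolerance = 1e-8)
  # round-trip reconstruction error equals the orthogonal-complement norm
  set.seed(2)
  x <- basis$mean + rnorm(length(basis$mean))
  a <- project_modes(x, basis)
  recon <- reconstruct_from_modes(a, basis)
  resid <- (x - basis$mean) -
    basis$components %*% crossprod(basis$components, x - basis$mean)
  expect_equal(sqrt(sum((x - recon)^2)), sqrt(sum(resid^2)),
               tolerance = 1e-9)
  expect_error(project_modes(x[-1], basis), "mismatch")
})
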