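# Procedural fixtures: a self-contained generative "world" that renders
# single-worm videos with known ground-truth centerlines, so that every
# pipeline stage can be exercised and scored without any external
# recording. The worm's posture lives in a three-mode space (two traveling
# -wave modes plus a turning mode), mimicking the dominant eigenworm
# structure of real crawling, with scheduled deep-coiling bouts.

#' Parameters of the procedural fixture world
#'
#' Defaults emulate a standard single-worm tracker recording scaled to a
#' small canvas: a dark worm (about 80% of the canvas in length) on a light
#' background, imaged at 30 Hz with mild sensor noise and optical blur; the
#' undulation has a wavelength of 0.65 body lengths and about 0.5 Hz
#' temporal frequency, and coiling bouts push the turning mode deep into
#' the omega/delta band.
#'
#' @param L canvas side in pixels.
#' @param worm_length worm length in pixels (default `0.8 * L`).
#' @param widths3 head/midbody/tail widths in pixels (default scaled from
#'   the worm length, midbody about 1/13 of the length).
#' @param n_angles number of tangent angles (100, the standard posture
#'   dimension).
#' @param wavelength_frac undulation wavelength as a fraction of the body.
#' @param wave_amp mean amplitude of the two wave modes, in eigen units.
#' @param frequency_hz temporal frequency of the body wave.
#' @param coil_a3_max deepest scheduled turning-mode amplitude.
#' @param coil_rate_hz expected rate of coiling bouts (per second).
#' @param coil_duration_s duration of a coiling bout.
#' @param posture_noise scale of the residual posture fluctuations (the
#'   baseline turning-mode wander and the smooth shape noise); 0 gives a
#'   perfectly regular worm.
#' @param label_a3_threshold frames with `|a_3|` below this are "labeled"
#'   (classical-tracker coverage: simple, non-coiled postures only).
#' @param background,body_dark background and worm-core gray levels.
#' @param noise_sd,blur_sigma sensor noise and optical blur.
#' @param texture_amp,texture_freq longitudinal body texture.
#' @param fps frame rate (Hz).
#' @param duration_s video duration (seconds).
#' @param seed integer seed; the whole world is deterministic given it.
#' @return list of class `fixture_world`.
#' @export
fixture_world <- function(L = 48, worm_length = 0.8 * L,
                          widths3 = worm_length * c(0.06, 0.085, 0.05),
                          n_angles = 100, wavelength_frac = 0.65,
                          wave_amp = 4.5, frequency_hz = 0.5,
                          coil_a3_max = 26, coil_rate_hz = 0.05,
                          coil_duration_s = 2.5, posture_noise = 1,
                          label_a3_threshold = 10,
                          background = 0.85, body_dark = 0.25,
                          noise_sd = 0.015, blur_sigma = 0.5,
                          texture_amp = 0.05, texture_freq = 3,
                          fps = 30, duration_s = 20, seed = 1) {
  stopifnot(L >= 32, worm_length > 0, all(widths3 > 0), fps > 0,
            duration_s > 0)
  if (worm_length / pi + max(widths3) > L / 2 + 2)
    stop("worm too large for the canvas: a coiled posture would not fit")
  structure(as.list(environment()), class = "fixture_world")
}

# orthonormal posture modes: two wave modes and a centered-ramp turning
# mode, evaluated at the segment midpoints
.fixture_modes <- function(world) {
  N <- world$n_angles
  s <- (seq_len(N) - 0.5) / N
  raw <- cbind(sin(2 * pi * s / world$wavelength_frac),
               cos(2 * pi * s / world$wavelength_frac),
               s - 0.5)
  qr.Q(qr(raw))
}

# smooth small-amplitude shape noise from a few high-order Fourier terms
.fixture_shape_noise <- function(N, n_shapes, sd = 0.05) {
  s <- (seq_len(N) - 0.5) / N
  H <- cbind(sin(2 * pi * 3 * s), cos(2 * pi * 3 * s),
             sin(2 * pi * 4 * s), cos(2 * pi * 4 * s))
  coef <- matrix(stats::rnorm(n_shapes * 4, sd = sd * sqrt(N) / 2),
                 n_shapes, 4)
  coef %*% t(H)
}

#' Draw crawl-like shapes for building the fixture eigenbasis
#'
#' Postures representative of ordinary crawling (wave modes dominant, mild
#' turning amplitudes), from which the fixture's own eigenworm basis is
#' computed; the induced component ordering matches the canonical one
#' (wave, wave, turn).
#'
#' @param world a [fixture_world()].
#' @param n number of shapes.
#' @param seed integer seed.
#' @return `n x n_angles` matrix of centered (rotation-free) angle vectors.
#' @export
fixture_basis_shapes <- function(world, n = 1500, seed = world$seed) {
  U <- .fixture_modes(world)
  withr::with_seed(seed, {
    amp <- stats::runif(n, 0.7, 1.3) * world$wave_amp
    ph <- stats::runif(n, 0, 2 * pi)
    a3 <- stats::rnorm(n, 0, 2.5)
    noise <- .fixture_shape_noise(world$n_angles, n)
    cbind(amp * cos(ph), amp * sin(ph), a3) %*% t(U) + noise
  })
}

#' Draw a coil-balanced shape corpus for fitting the shape model
#'
#' Equal representation across the turning-mode range: `a_3` is uniform
#' over `(-coil_a3_max, coil_a3_max)`, emulating a shape library balanced
#' between coiled and uncoiled postures and sampled uniformly in body
#' curvature.
#'
#' @inheritParams fixture_basis_shapes
#' @return `n x n_angles` matrix of centered angle vectors.
#' @export
fixture_corpus <- function(world, n = 5000, seed = world$seed + 1) {
  U <- .fixture_modes(world)
  withr::with_seed(seed, {
    amp <- stats::runif(n, 0.7, 1.3) * world$wave_amp
    ph <- stats::runif(n, 0, 2 * pi)
    a3 <- stats::runif(n, -world$coil_a3_max, world$coil_a3_max)
    noise <- .fixture_shape_noise(world$n_angles, n)
    cbind(amp * cos(ph), amp * sin(ph), a3) %*% t(U) + noise
  })
}

#' Eigenworm basis of the fixture world
#' @inheritParams fixture_basis_shapes
#' @param d number of components (default 5).
#' @return a `worm_eigenbasis` computed from [fixture_basis_shapes()].
#' @export
fixture_eigenbasis <- function(world, n = 1500, d = 5, seed = world$seed) {
  compute_eigenbasis(fixture_basis_shapes(world, n, seed), d = d,
                     source = "procedural fixture crawl shapes")
}

# per-frame turning-mode schedule: smooth baseline plus Hann-window bouts
.fixture_a3_schedule <- function(world, n_frames) {
  a3 <- stats::filter(stats::rnorm(n_frames, 0, 1.2), rep(1 / 8, 8),
                      circular = TRUE)
  a3 <- as.numeric(a3) * 2 * world$posture_noise
  bout_len <- round(world$coil_duration_s * world$fps)
  n_bouts <- stats::rpois(1, world$coil_rate_hz * n_frames / world$fps)
  if (n_bouts > 0 && n_frames > bout_len + 2) {
    starts <- sort(sample.int(n_frames - bout_len, n_bouts))
    for (s in starts) {
      amp <- stats::runif(1, 15, world$coil_a3_max) * sample(c(-1, 1), 1)
      w <- 0.5 * (1 - cos(2 * pi * seq_len(bout_len) / (bout_len + 1)))
      idx <- s:(s + bout_len - 1)
      a3[idx] <- a3[idx] + amp * w
    }
  }
  a3
}

#' Generate a procedural worm video with ground truth
#'
#' Renders a smoothly undulating worm (wave-mode rotation at the world's
#' frequency, scheduled high-`|a_3|` coiling bouts, slow drift of the
#' global orientation) as a shaded body with noise and blur, worm-centered
#' on an `L x L` canvas. Ground-truth centerlines are emitted for every
#' frame; only non-coiled frames (`|a_3|` below the world threshold) are
#' marked "labeled", mimicking classical-tracker coverage.
#'
#' @param world a [fixture_world()].
#' @return object of class `fixture_video`: `frames` (`L x L x T` array),
#'   `truth` (`T x N` angle matrix, head to tail, including the global
#'   orientation), `a3` (scheduled turning mode), `labeled` (logical),
#'   `skeletons` (list of `T` skeleton coordinate matrices), `centroid`
#'   (`T x 2` virtual plate coordinates), `widths3`, `fps`, `world`.
#' @export
generate_fixture_video <- function(world) {
  n_frames <- round(world$duration_s * world$fps)
  N <- world$n_angles
  U <- .fixture_modes(world)
  withr::with_seed(world$seed, {
    phase0 <- stats::runif(1, 0, 2 * pi)
    amp <- world$wave_amp * stats::runif(1, 0.9, 1.1)
    a3 <- .fixture_a3_schedule(world, n_frames)
    g <- cumsum(stats::rnorm(n_frames, 0, 0.02))  # global orientation drift
    noise_seeds <- sample.int(.Machine$integer.max %/% 2, n_frames)
    # temporally smooth shape fluctuations: low-pass filtered coefficients
    # on the same high-order Fourier terms used for static shape noise
    s <- (seq_len(N) - 0.5) / N
    H <- cbind(sin(2 * pi * 3 * s), cos(2 * pi * 3 * s),
               sin(2 * pi * 4 * s), cos(2 * pi * 4 * s))
    klen <- max(3, round(world$fps / 3))
    coef <- apply(matrix(stats::rnorm(n_frames * 4), n_frames, 4), 2,
                  function(z) {
                    sm <- stats::filter(z, rep(1 / klen, klen),
                                        circular = TRUE)
                    as.numeric(sm) / stats::sd(sm, na.rm = TRUE)
                  })
    shape_noise <- (coef * world$posture_noise * 0.05 * sqrt(N) / 2) %*%
      t(H)
  })
  t_s <- (seq_len(n_frames) - 1) / world$fps
  phase <- phase0 + 2 * pi * world$frequency_hz * t_s
  truth <- cbind(amp * cos(phase), amp * sin(phase), a3) %*% t(U) +
    shape_noise + g
  widths <- interpolate_widths(world$widths3, N + 1)
  dS <- world$worm_length / N
  frames <- array(0, c(world$L, world$L, n_frames))
  skeletons <- vector("list", n_frames)
  centroid <- matrix(0, n_frames, 2)
  pos <- c(0, 0)
  for (i in seq_len(n_frames)) {
    pts <- angles_to_skeleton(truth[i, ], dS = dS)
    skel <- .center_skeleton(pts, world$L)
    skeletons[[i]] <- skel
    frames[, , i] <- cpp_fixture_frame(
      skel, widths, world$L, world$background, world$body_dark,
      world$texture_amp, world$texture_freq, world$noise_sd,
      world$blur_sigma, noise_seeds[i])
    # virtual plate-frame centroid: the worm advances along its mean body
    # axis as the wave phase progresses
    heading <- mean(truth[i, ])
    pos <- pos + (world$worm_length * world$frequency_hz / world$fps) *
      0.35 * c(cos(heading), sin(heading))
    centroid[i, ] <- pos + colMeans(skel)
  }
  structure(list(frames = frames, truth = truth, a3 = a3,
                 labeled = abs(a3) < world$label_a3_threshold,
                 skeletons = skeletons, centroid = centroid,
                 widths3 = world$widths3, fps = world$fps, world = world),
            class = "fixture_video")
}

#' @export
print.fixture_video <- function(x, ...) {
  cat(sprintf(
    "Fixture video: %d frames of %dx%d px at %g Hz (%.0f%% labeled)\n",
    dim(x$frames)[3], nrow(x$frames), ncol(x$frames), x$fps,
    100 * mean(x$labeled)))
  invisible(x)
}

#' True body support of a fixture posture
#'
#' The set of pixels actually darkened by the worm body in a noiseless,
#' blur-free rendering; the ground truth against which segmentation masks
#' are scored.
#'
#' @param world a [fixture_world()].
#' @param skeleton skeleton coordinate matrix (canvas pixels).
#' @param cut minimum darkening below the background that counts as body.
#' @return logical `L x L` mask.
#' @export
fixture_body_mask <- function(world, skeleton, cut = 0.03) {
  widths <- interpolate_widths(world$widths3, nrow(skeleton))
  clean <- cpp_fixture_frame(skeleton, widths, world$L, world$background,
                             world$body_dark, 0, 0, 0, 0, 1L)
  clean < (world$background - cut)
}

#' Build rendering templates from a fixture video
#'
#' Picks labeled (non-coiled) frames, standardizes them with the
#' preprocessing stage, and attaches the ground-truth skeleton (shifted
#' into the processed frame) and widths as labels.
#'
#' @param video a `fixture_video`.
#' @param n number of reference frames.
#' @param seed integer seed for the frame choice.
#' @return list of [reference_frame()] objects.
#' @export
fixture_reference_frames <- function(video, n = 12, seed = 1) {
  cand <- which(video$labeled)
  if (length(cand) == 0) stop("video has no labeled frames")
  pick <- withr::with_seed(seed,
    sample(cand, min(n, length(cand))))
  out <- list()
  for (i in pick) {
    pf <- process_frame(video$frames[, , i], L = video$world$L)
    if (is.null(pf)) next
    skel <- sweep(video$skeletons[[i]], 2, pf$offset)
    L <- pf$L
    skel[, 1] <- pmin(pmax(skel[, 1], 1), L)
    skel[, 2] <- pmin(pmax(skel[, 2], 1), L)
    out[[length(out) + 1]] <- reference_frame(pf, skel, video$widths3)
  }
  if (length(out) == 0) stop("no usable reference frames")
  out
}

#' Simulate noisy network predictions from ground truth
#'
#' Stand-in for a trained network in tests of the temporal post-processing:
#' each frame's prediction is the true centerline plus angular noise, with
#' the head-tail orientation randomized (as network output would be).
#'
#' @param truth `T x N` matrix of true centerlines.
#' @param sd angular noise, radians.
#' @param seed integer seed.
#' @return list of prediction pairs as produced by [predict_centerlines()].
#' @export
simulate_predictions <- function(truth, sd = 0.05, seed = 1) {
  truth <- as.matrix(truth)
  withr::with_seed(seed, {
    lapply(seq_len(nrow(truth)), function(i) {
      theta <- wrap_angles(truth[i, ] + stats::rnorm(ncol(truth), 0, sd))
      if (stats::runif(1) < 0.5) theta <- flip_centerline(theta)
      list(theta = theta, theta_flipped = flip_centerline(theta),
           frame_index = i)
    })
  })
}
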