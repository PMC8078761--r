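# Synthetic worm-image generation ("reverse skeletonization"): bend the
# texture of a labeled reference frame onto an arbitrary target centerline
# by warping small rectangular patches along the body, blending overlaps,
# masking protrusions with the expected worm outline and median-filtering
# the seams.

#' Rendering and augmentation parameters for the image synthesizer
#'
#' @param step patch spacing in skeleton indices; `NULL` (default) uses
#'   `N_S / 16`, rounded, following the trade-off between patch overlap and
#'   per-patch curvature.
#' @param w_multiplier patch width as a multiple of the local worm width
#'   (default 1.2, so patches include background pixels around the body).
#' @param augment logical; apply the stochastic augmentations below.
#' @param translate_frac maximum target-skeleton translation, as a fraction
#'   of the image side (uniform in `[0, translate_frac]`).
#' @param length_range multiplicative worm-length jitter (uniform).
#' @param thickness_range range replacing `w_multiplier` under augmentation.
#' @param flip_draw_prob probability of drawing patches head-first instead
#'   of tail-first.
#' @param blur_prob probability of an extra Gaussian blur after rendering.
#' @param blur_frac blur kernel size range as a fraction of the image side.
#' @param blur_cap_px upper cap on the blur kernel, in pixels.
#' @param mask_pad widening (pixels) of the protrusion-clipping outline
#'   mask, so that the blurred halo copied with the texture patches is not
#'   cut to a hard edge.
#' @return a list of class `synth_params`.
#' @export
synth_params <- function(step = NULL, w_multiplier = 1.2, augment = TRUE,
                         translate_frac = 0.05,
                         length_range = c(0.9, 1.1),
                         thickness_range = c(1.1, 1.3),
                         flip_draw_prob = 0.5, blur_prob = 0.25,
                         blur_frac = c(0.03, 0.10), blur_cap_px = 13,
                         mask_pad = 1) {
  if (!is.null(step) && step < 1) stop("'step' must be at least 1")
  if (w_multiplier <= 1) stop("'w_multiplier' must exceed 1")
  structure(list(step = step, w_multiplier = w_multiplier, augment = augment,
                 translate_frac = translate_frac,
                 length_range = length_range,
                 thickness_range = thickness_range,
                 flip_draw_prob = flip_draw_prob, blur_prob = blur_prob,
                 blur_frac = blur_frac, blur_cap_px = blur_cap_px,
                 mask_pad = mask_pad),
            class = "synth_params")
}

#' Interpolate per-point worm widths from three landmark widths
#'
#' Worm trackers label the body width at the head, midbody and tail only.
#' The full width profile is constant up to the head landmark, linear
#' between landmarks, and constant after the tail landmark.
#'
#' @param widths3 numeric `(head, midbody, tail)` widths in pixels.
#' @param n_points number of skeleton points.
#' @param landmarks fractional arc-length positions of the three landmarks.
#' @return numeric width per skeleton point.
#' @export
interpolate_widths <- function(widths3, n_points,
                               landmarks = c(0.15, 0.5, 0.85)) {
  if (any(widths3 <= 0)) stop("widths must be positive")
  if (any(diff(landmarks) <= 0) || landmarks[1] <= 0 || landmarks[3] >= 1)
    stop("landmark fractions must be increasing and inside (0, 1)")
  fr <- seq(0, 1, length.out = n_points)
  stats::approx(x = c(0, landmarks, 1),
                y = widths3[c(1, 1, 2, 3, 3)],
                xout = fr)$y
}

#' Expected worm outline mask
#'
#' Union of per-segment convex quadrilaterals (skeleton points offset by
#' half the local width along the segment normals) with filled circles at
#' the two extremities; used to clip patch-warping protrusions and to
#' bound template crops.
#'
#' @param skeleton `N_S x 2` coordinate matrix (1-based pixel coordinates).
#' @param widths per-point widths (pixels).
#' @param L canvas side.
#' @return logical `L x L` mask.
#' @export
worm_outline_mask <- function(skeleton, widths, L) {
  skeleton <- as.matrix(skeleton)
  seg <- sqrt(diff(skeleton[, 1])^2 + diff(skeleton[, 2])^2)
  if (sum(seg) < 1e-9) stop("degenerate skeleton of zero length")
  if (any(skeleton < 0.5) || any(skeleton > L + 0.5))
    warning("skeleton exits the canvas; mask clipped")
  cpp_outline_mask(skeleton, widths, L) > 0
}

#' Bundle a processed frame with its labels as a rendering template
#'
#' @param processed a `processed_frame`.
#' @param skeleton `N_S x 2` labeled centerline coordinates (head to tail,
#'   in processed-image pixels).
#' @param widths3 labeled `(head, midbody, tail)` widths in pixels.
#' @return object of class `reference_frame` with the precomputed width
#'   profile `ww` and worm length.
#' @export
reference_frame <- function(processed, skeleton, widths3) {
  stopifnot(inherits(processed, "processed_frame"))
  skeleton <- as.matrix(skeleton)
  n <- nrow(skeleton)
  if (n < 20)
    warning("reference skeleton has fewer than 20 points; synthetic images ",
            "will be simplistic")
  if (n > 200 || n < 20)
    warning("recommended range for N_S is roughly 50-100 points")
  L <- processed$L
  if (any(skeleton < 1) || any(skeleton > L))
    stop("reference skeleton must lie inside the processed image")
  structure(list(
    processed = processed, skeleton = skeleton, widths3 = widths3,
    ww = interpolate_widths(widths3, n),
    worm_length = sum(sqrt(diff(skeleton[, 1])^2 + diff(skeleton[, 2])^2))
  ), class = "reference_frame")
}

# center a skeleton's bounding box on the canvas center plus a shift; the
# centering translation is rounded to whole pixels so that an identity
# warp stays resampling-exact
.center_skeleton <- function(pts, L, shift = c(0, 0)) {
  bx <- (min(pts[, 1]) + max(pts[, 1])) / 2
  by <- (min(pts[, 2]) + max(pts[, 2])) / 2
  cbind(pts[, 1] + round((L + 1) / 2 - bx) + shift[1],
        pts[, 2] + round((L + 1) / 2 - by) + shift[2])
}

.skeleton_fits <- function(pts, L, margin = 1) {
  all(pts >= 1 + margin - 1) && all(pts <= L - margin + 1)
}

#' Render a synthetic worm image in a target posture
#'
#' Builds the target skeleton from the tangent angles (segment length =
#' reference worm length / (N_S - 1)), centers it on the canvas, warps
#' texture patches from the reference frame onto it, blends overlaps at
#' weight 0.5, masks protrusions with the expected outline, median-filters
#' (window 3) and sets non-worm pixels to the reference background. With
#' `params$augment` the translation/length/thickness/draw-order/blur
#' augmentations are applied, driven by `seed`.
#'
#' @param ref a [reference_frame()].
#' @param target numeric vector of target tangent angles.
#' @param params a [synth_params()] list.
#' @param seed integer seed for the augmentations (ignored when
#'   `params$augment` is `FALSE`).
#' @return object of class `synthetic_sample`: `image` (`L x L` matrix),
#'   `target`, `target_flipped`, `target_skeleton`, `provenance`.
#' @export
render_synthetic <- function(ref, target, params = synth_params(),
                             seed = 1) {
  stopifnot(inherits(ref, "reference_frame"))
  n_s <- nrow(ref$skeleton)
  L <- ref$processed$L
  step <- params$step
  if (is.null(step)) step <- max(1L, round(n_s / 16))

  if (params$augment) {
    aug <- withr::with_seed(seed, list(
      shift_r = stats::runif(1, 0, params$translate_frac * L),
      shift_phi = stats::runif(1, 0, 2 * pi),
      len_mult = stats::runif(1, params$length_range[1],
                              params$length_range[2]),
      wmult = stats::runif(1, params$thickness_range[1],
                           params$thickness_range[2]),
      head_last = stats::runif(1) >= params$flip_draw_prob,
      do_blur = stats::runif(1) < params$blur_prob,
      blur_k = stats::runif(1, params$blur_frac[1], params$blur_frac[2])
    ))
    shift <- aug$shift_r * c(cos(aug$shift_phi), sin(aug$shift_phi))
  } else {
    aug <- list(len_mult = 1, wmult = params$w_multiplier, head_last = TRUE,
                do_blur = FALSE)
    shift <- c(0, 0)
  }

  dS <- ref$worm_length * aug$len_mult / (n_s - 1)
  pts <- angles_to_skeleton(target, dS = dS)
  if (nrow(pts) != n_s) pts <- resample_skeleton(pts, n_s)
  tgt <- .center_skeleton(pts, L, shift)
  if (!.skeleton_fits(tgt, L)) {
    tgt <- .center_skeleton(pts, L)  # drop the translation augmentation
    if (!.skeleton_fits(tgt, L, margin = 0))
      stop("target skeleton exceeds the canvas even when centered")
  }

  rend <- cpp_render_synth(ref$processed$image, ref$skeleton, tgt, ref$ww,
                           aug$wmult, as.integer(step), L,
                           ref$processed$background_value, aug$head_last,
                           params$mask_pad)
  img <- rend$image
  if (isTRUE(aug$do_blur)) {
    k <- min(round(aug$blur_k * L), params$blur_cap_px)
    sigma <- max(0.3 * ((k - 1) * 0.5 - 1) + 0.8, 0.3)
    img <- cpp_gauss_blur(img, sigma)
  }
  structure(list(
    image = img, mask = rend$mask, target = target,
    target_flipped = flip_centerline(target), target_skeleton = tgt,
    provenance = list(seed = seed, step = step, augment = params$augment,
                      aug = aug)
  ), class = "synthetic_sample")
}

#' Generate a synthetic training set from a shape model
#'
#' For each sample a posture is drawn from the mixture model, a global
#' orientation (uniform on `(0, 2*pi]`) is added to all angles, the head end
#' is assigned randomly, a reference frame is picked from a bounded pool
#' (at most `max_refs` templates) and the image is rendered with
#' augmentations. Deterministic given `seed`; failed renders are skipped
#' and counted.
#'
#' @param refs list of [reference_frame()] templates.
#' @param model a fitted `worm_shape_model`.
#' @param n number of samples.
#' @param params a [synth_params()] list.
#' @param seed integer seed.
#' @param max_refs reference-pool cap (default 1000).
#' @return list with `images` (`L x L x n` array), `targets` (`n x N`
#'   matrix of continuous angle labels), `meta` (data frame: reference
#'   index, rotation, head flip, seed) and `n_failed`.
#' @export
generate_training_set <- function(refs, model, n, params = synth_params(),
                                  seed = 1, max_refs = 1000) {
  stopifnot(length(refs) >= 1)
  L <- refs[[1]]$processed$L
  N <- ncol(model$means)
  if (n == 0)
    return(list(images = array(0, c(L, L, 0)), targets = matrix(0, 0, N),
                meta = data.frame(), n_failed = 0L))
  if (length(refs) > max_refs)
    refs <- withr::with_seed(seed, sample(refs, max_refs))
  shapes <- sample_shapes(model, n, seed = seed)
  draws <- withr::with_seed(seed + 1L, list(
    rot = stats::runif(n, 0, 2 * pi),
    flip = stats::runif(n) < 0.5,
    ref = sample.int(length(refs), n, replace = TRUE),
    rseed = sample.int(.Machine$integer.max %/% 2, n)
  ))
  images <- array(0, c(L, L, n))
  targets <- matrix(0, n, N)
  failed <- logical(n)
  for (i in seq_len(n)) {
    theta <- shapes[i, ] + draws$rot[i]
    if (draws$flip[i]) theta <- rev(theta) + pi  # continuous head reassignment
    s <- tryCatch(
      render_synthetic(refs[[draws$ref[i]]], theta, params,
                       seed = draws$rseed[i]),
      error = function(e) NULL)
    if (is.null(s)) { failed[i] <- TRUE; next }
    images[, , i] <- s$image
    targets[i, ] <- theta
  }
  keep <- !failed
  list(images = images[, , keep, drop = FALSE],
       targets = targets[keep, , drop = FALSE],
       meta = data.frame(ref = draws$ref, rotation = draws$rot,
                         flipped = draws$flip, seed = draws$rseed)[keep, ],
       n_failed = sum(failed))
}

#' Write a training set to sharded archives with a manifest
#'
#' @param training output of [generate_training_set()].
#' @param dir output directory (created if needed).
#' @param shard_size samples per shard.
#' @return invisible manifest list (also written as `manifest.json`).
#' @export
write_training_shards <- function(training, dir, shard_size = 5000) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(training$images)[3]
  starts <- seq(1, max(n, 1), by = shard_size)
  files <- character(0)
  for (k in seq_along(starts)) {
    idx <- starts[k]:min(starts[k] + shard_size - 1, n)
    if (n == 0) break
    f <- file.path(dir, sprintf("shard_%03d.rds", k))
    saveRDS(list(images = training$images[, , idx, drop = FALSE],
                 targets = training$targets[idx, , drop = FALSE]), f)
    files <- c(files, basename(f))
  }
  manifest <- list(n = n, shards = files, shard_size = shard_size,
                   n_failed = training$n_failed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
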