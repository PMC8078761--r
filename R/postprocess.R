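# Post-prediction: score predictions by synthetic reconstruction against
# the input image, discard outliers, resolve head-tail orientation with
# temporal information and labeled frames, interpolate small gaps and
# smooth the angle series.

#' Image error of a candidate centerline
#'
#' Renders the candidate posture with the synthesizer (no augmentations),
#' crops the rendering to the worm bounding box plus 2 px padding and
#' slides it over the original image, computing the normalized correlation
#' coefficient at every placement. The image error is `1 - |c|_max`, in
#' `[0, 1]`; anti-correlated matches (reversed-intensity images) therefore
#' also count as good reconstructions. The location of the maximum gives
#' the predicted skeleton offset in the original frame.
#'
#' @param original a `processed_frame` (or plain image matrix).
#' @param candidate angle vector of the predicted centerline.
#' @param ref a [reference_frame()] (the nearest labeled frame in time).
#' @return list with `error`, `offset` (x, y placement of the template
#'   origin, 0-based) and `corr` (the signed correlation at the maximum).
#' @export
image_error <- function(original, candidate, ref) {
  img <- if (inherits(original, "processed_frame")) original$image
         else as.matrix(original)
  syn <- render_synthetic(ref, candidate,
                          synth_params(augment = FALSE))
  idx <- which(syn$mask, arr.ind = TRUE)
  pad <- 2
  y0 <- max(1, min(idx[, 1]) - pad)
  y1 <- min(nrow(syn$mask), max(idx[, 1]) + pad)
  x0 <- max(1, min(idx[, 2]) - pad)
  x1 <- min(ncol(syn$mask), max(idx[, 2]) + pad)
  templ <- syn$image[y0:y1, x0:x1]
  cmap <- cpp_ncc_map(img, templ)
  best <- which(abs(cmap) == max(abs(cmap)), arr.ind = TRUE)[1, ]
  list(error = 1 - max(abs(cmap)),
       offset = c(x = unname(best[2]) - 1, y = unname(best[1]) - 1),
       corr = cmap[best[1], best[2]])
}

#' Score both orientations of a prediction pair
#' @param original a `processed_frame`.
#' @param pair prediction pair (`theta`, `theta_flipped`).
#' @param ref a [reference_frame()].
#' @return list with per-orientation errors and the better orientation.
#' @export
image_error_pair <- function(original, pair, ref) {
  e1 <- image_error(original, pair$theta, ref)
  e2 <- image_error(original, pair$theta_flipped, ref)
  list(error = c(e1$error, e2$error),
       best = if (e1$error <= e2$error) 1L else 2L,
       offset = if (e1$error <= e2$error) e1$offset else e2$offset)
}

#' Select an image-error threshold from labeled-frame errors
#'
#' Reconstructing labeled (trusted) frames from their own labels gives a
#' distribution of low image errors; the discard threshold should sit well
#' above it. The default of 0.3 retains the bulk of honest predictions
#' while removing clearly failed reconstructions; inspect the returned
#' distribution (or plot) before overriding.
#'
#' @param errors_on_labeled image errors of labeled frames reconstructed
#'   from their own labels.
#' @param threshold candidate threshold (default 0.3).
#' @param plot draw a histogram of the error distribution.
#' @return object of class `error_threshold` with the threshold, the error
#'   distribution and the fraction of labeled frames retained.
#' @export
choose_threshold <- function(errors_on_labeled, threshold = 0.3,
                             plot = FALSE) {
  if (length(errors_on_labeled) == 0) {
    warning("no labeled-frame errors supplied; keeping the default ",
            "threshold of 0.3")
    errors_on_labeled <- numeric(0)
  }
  retained <- if (length(errors_on_labeled))
    mean(errors_on_labeled <= threshold) else NA_real_
  if (plot && length(errors_on_labeled)) {
    graphics::hist(errors_on_labeled, breaks = 30,
                   main = "Image error on labeled frames",
                   xlab = "image error"); graphics::abline(v = threshold,
                                                           lty = 2)
  }
  structure(list(threshold = threshold, errors = sort(errors_on_labeled),
                 retained_fraction = retained),
            class = "error_threshold")
}

#' @export
print.error_threshold <- function(x, ...) {
  cat(sprintf("Image-error threshold %.2f", x$threshold))
  if (length(x$errors))
    cat(sprintf(" (retains %.1f%% of %d labeled frames; median error %.3f)",
                100 * x$retained_fraction, length(x$errors),
                stats::median(x$errors)))
  cat("\n")
  invisible(x)
}

#' Group predictions into segments of temporally consistent orientation
#'
#' Greedy pass over the time-ordered prediction pairs: within a segment the
#' orientation (prediction or its flip) minimizing the mean absolute angle
#' distance to the last aligned frame is chosen; when both orientations are
#' further than the threshold (default 30 degrees) the scan looks up to
#' `lookahead_s` seconds ahead (intervening frames become gaps) before
#' closing the segment and restarting with a random orientation. Segments
#' shorter than `min_duration_s` are discarded.
#'
#' @param pairs list of prediction pairs (`theta`, `theta_flipped`);
#'   elements may be `NULL` for frames discarded by the image error.
#' @param fps frame rate in Hz.
#' @param threshold_deg continuity threshold in degrees (default 30).
#' @param lookahead_s forward scan horizon in seconds (default 0.2).
#' @param min_duration_s minimum segment duration in seconds (default 0.2).
#' @param seed seed for the random segment-start orientations.
#' @return list of class `pose_segments`; each segment has `frames`
#'   (indices), `flipped` (chosen orientation per frame) and `angles`
#'   (matrix of chosen centerlines).
#' @export
build_segments <- function(pairs, fps, threshold_deg = 30,
                           lookahead_s = 0.2, min_duration_s = 0.2,
                           seed = 1) {
  if (fps <= 0) stop("'fps' must be positive")
  thr <- threshold_deg * pi / 180
  lookahead <- max(1L, floor(lookahead_s * fps))
  min_frames <- ceiling(min_duration_s * fps)
  n <- length(pairs)
  rand_flip <- withr::with_seed(seed, stats::runif(n) < 0.5)

  segments <- list()
  cur <- NULL   # list(frames, flipped, angles, last)
  close_segment <- function() {
    if (!is.null(cur) && length(cur$frames) >= min_frames)
      segments[[length(segments) + 1L]] <<- list(
        frames = cur$frames, flipped = cur$flipped,
        angles = do.call(rbind, cur$angles))
    cur <<- NULL
  }
  i <- 1L
  while (i <= n) {
    p <- pairs[[i]]
    if (is.null(p)) { i <- i + 1L; next }
    if (is.null(cur)) {
      fl <- rand_flip[i]
      th <- if (fl) p$theta_flipped else p$theta
      cur <- list(frames = i, flipped = fl, angles = list(th), last = th)
      i <- i + 1L; next
    }
    d0 <- mean_abs_angle_distance(cur$last, p$theta)
    d1 <- mean_abs_angle_distance(cur$last, p$theta_flipped)
    if (min(d0, d1) <= thr) {
      fl <- d1 < d0   # exact ties keep the unflipped incumbent labeling
      th <- if (fl) p$theta_flipped else p$theta
      cur$frames <- c(cur$frames, i); cur$flipped <- c(cur$flipped, fl)
      cur$angles <- c(cur$angles, list(th)); cur$last <- th
      i <- i + 1L; next
    }
    # scan ahead for a frame close to the last aligned pose
    found <- FALSE
    horizon <- min(n, i + lookahead)
    j <- i + 1L
    while (j <= horizon) {
      q <- pairs[[j]]
      if (!is.null(q)) {
        e0 <- mean_abs_angle_distance(cur$last, q$theta)
        e1 <- mean_abs_angle_distance(cur$last, q$theta_flipped)
        if (min(e0, e1) <= thr) { found <- TRUE; break }
      }
      j <- j + 1L
    }
    if (found) i <- j          # frames i..j-1 become a gap
    else { close_segment() }   # restart at frame i
  }
  close_segment()
  n_angles <- NA_integer_
  for (p in pairs) if (!is.null(p)) { n_angles <- length(p$theta); break }
  structure(segments, class = "pose_segments", fps = fps,
            n_frames = n, n_angles = n_angles)
}

#' @export
print.pose_segments <- function(x, ...) {
  cov <- sum(vapply(x, function(s) length(s$frames), integer(1)))
  cat(sprintf("%d pose segments covering %d/%d frames (%.1f%%)\n",
              length(x), cov, attr(x, "n_frames"),
              100 * cov / max(1, attr(x, "n_frames"))))
  invisible(x)
}

# head-to-tail displacement vector of a centerline (unit-step skeleton)
.head_tail_vector <- function(theta) {
  pts <- angles_to_skeleton(theta, dS = 1)
  pts[nrow(pts), ] - pts[1, ]
}

#' Resolve the global head-tail orientation of each segment
#'
#' Within a segment the pose is temporally consistent but the head label is
#' arbitrary. Segments overlapping labeled frames are flipped, as a whole,
#' to maximize the cosine similarity between the head-to-tail vectors of
#' the predictions and the labels. Remaining segments inherit the
#' orientation of the nearest already-aligned neighboring segment by
#' comparing their two closest frames; segments that cannot be resolved are
#' flagged.
#'
#' @param segments a `pose_segments` object.
#' @param labeled_frames integer vector of labeled frame indices.
#' @param labeled_angles matrix with one labeled centerline (head to tail)
#'   per row, aligned with `labeled_frames`.
#' @return list of class `oriented_segments`; each segment gains
#'   `orientation_source` (`"labels"`, `"neighbor"` or `"unresolved"`) and
#'   its `angles`/`flipped` are updated in place.
#' @export
orient_segments <- function(segments, labeled_frames, labeled_angles) {
  labeled_angles <- as.matrix(labeled_angles)
  segs <- unclass(segments)
  source <- rep("unresolved", length(segs))
  cosim <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  flip_segment <- function(s) {
    s$angles <- t(apply(s$angles, 1, flip_centerline))
    s$flipped <- !s$flipped
    s
  }
  # pass 1: segments overlapping labels
  for (k in seq_along(segs)) {
    common <- intersect(segs[[k]]$frames, labeled_frames)
    if (length(common) == 0) next
    sims <- vapply(common, function(f) {
      cosim(.head_tail_vector(segs[[k]]$angles[match(f, segs[[k]]$frames), ]),
            .head_tail_vector(labeled_angles[match(f, labeled_frames), ]))
    }, numeric(1))
    if (mean(sims) < 0) segs[[k]] <- flip_segment(segs[[k]])
    source[k] <- "labels"
  }
  # pass 2: propagate to label-less segments from aligned neighbors
  repeat {
    changed <- FALSE
    for (k in seq_along(segs)) {
      if (source[k] != "unresolved") next
      neigh <- c(k - 1L, k + 1L)
      neigh <- neigh[neigh >= 1 & neigh <= length(segs)]
      neigh <- neigh[source[neigh] != "unresolved"]
      if (length(neigh) == 0) next
      # nearest aligned neighbor in time
      gap <- vapply(neigh, function(j)
        min(abs(range(segs[[j]]$frames) - range(segs[[k]]$frames))),
        numeric(1))
      j <- neigh[which.min(gap)]
      if (j < k) {
        u <- segs[[j]]$angles[nrow(segs[[j]]$angles), ]
        v <- segs[[k]]$angles[1, ]
      } else {
        u <- segs[[j]]$angles[1, ]
        v <- segs[[k]]$angles[nrow(segs[[k]]$angles), ]
      }
      if (cosim(.head_tail_vector(u), .head_tail_vector(v)) < 0)
        segs[[k]] <- flip_segment(segs[[k]])
      source[k] <- "neighbor"
      changed <- TRUE
    }
    if (!changed) break
  }
  if (all(source == "unresolved") && length(segs) > 0)
    warning("no labels overlap any segment; head-tail orientation is ",
            "unresolved everywhere")
  for (k in seq_along(segs)) segs[[k]]$orientation_source <- source[k]
  structure(segs, class = "oriented_segments",
            fps = attr(segments, "fps"),
            n_frames = attr(segments, "n_frames"),
            n_angles = attr(segments, "n_angles"))
}

#' Assemble oriented segments into a per-frame angle series
#' @param oriented an `oriented_segments` object.
#' @return matrix `n_frames x N` with `NA` rows for uncovered frames.
#' @export
segments_to_series <- function(oriented) {
  n <- attr(oriented, "n_frames")
  N <- if (length(oriented) > 0) ncol(oriented[[1]]$angles)
       else attr(oriented, "n_angles")
  out <- matrix(NA_real_, n, max(N, 1, na.rm = TRUE))
  for (s in oriented) out[s$frames, ] <- s$angles
  out
}

#' Interpolate small gaps in a centerline time series
#'
#' Gaps of at most `max_gap` frames are filled per angle index with a
#' third-order (cubic) spline through the neighboring valid frames; longer
#' gaps are left untouched.
#'
#' @param series matrix `T x N`, `NA` rows marking gaps.
#' @param max_gap maximum gap length to fill, in frames (default 4).
#' @param support number of valid frames used on each side of a gap.
#' @return the series with eligible gaps filled.
#' @export
interpolate_gaps <- function(series, max_gap = 4, support = 4) {
  series <- as.matrix(series)
  valid <- !is.na(series[, 1])
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$lengths)) {
    if (r$values[k] || r$lengths[k] > max_gap) next
    if (k == 1 || k == length(r$lengths)) next  # boundary gaps stay open
    left <- max(starts[k - 1], ends[k - 1] - support + 1):ends[k - 1]
    right <- starts[k + 1]:min(ends[k + 1], starts[k + 1] + support - 1)
    xs <- c(left, right)
    gap <- starts[k]:ends[k]
    for (j in seq_len(ncol(series))) {
      f <- stats::splinefun(xs, series[xs, j], method = "fmm")
      series[gap, j] <- f(gap)
    }
  }
  series
}

#' Smooth a centerline time series
#'
#' Per-angle-index Savitzky-Golay filter with third-order polynomials in
#' (nominally) 8-frame windows; the filter requires an odd window so the
#' default is the centered 9-frame window.
#'
#' @param series matrix `T x N` without gaps.
#' @param window filter window in frames (odd; default 9).
#' @param order polynomial order (default 3).
#' @return the smoothed series; returned unchanged (with a warning) when
#'   shorter than the window.
#' @export
smooth_angles <- function(series, window = 9, order = 3) {
  series <- as.matrix(series)
  if (window %% 2 == 0) {
    window <- window + 1
    warning("Savitzky-Golay windows must be odd; using ", window, " frames")
  }
  if (nrow(series) < window) {
    warning("series shorter than the smoothing window; returning unchanged")
    return(series)
  }
  apply(series, 2, function(col) signal::sgolayfilt(col, p = order,
                                                    n = window))
}
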