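#' @useDynLib nemapose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Image coordinate convention used throughout: x = column, y = row, with y
# increasing downward; tangent angles are atan2(dy, dx) so a positive angle
# turns clockwise on screen.

#' Wrap angles into (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return angles mapped to the principal interval `(-pi, pi]`.
#' @export
wrap_angles <- function(theta) {
  out <- atan2(sin(theta), cos(theta))
  # atan2 returns -pi for the branch point; map it to +pi
  out[out == -pi] <- pi
  out
}

#' Wrapped angular difference
#'
#' Computes `alpha - beta` on the circle, i.e. `atan2(sin(alpha - beta),
#' cos(alpha - beta))`, always in `(-pi, pi]`. This is the elementwise error
#' underlying every angular metric in the package.
#'
#' @param alpha,beta numeric vectors of angles in radians (recycled).
#' @return wrapped differences in radians.
#' @export
wrap_angle_diff <- function(alpha, beta) {
  wrap_angles(alpha - beta)
}

#' Convert tangent angles to skeleton coordinates
#'
#' Integrates a centerline of `N` tangent angles into `N + 1` equidistant
#' skeleton points: point `i + 1` is point `i` plus
#' `dS * (cos(theta_i), sin(theta_i))`.
#'
#' @param angles numeric vector of tangent angles, head to tail.
#' @param dS segment length in pixels (must be positive).
#' @param origin coordinates `(x, y)` of the first skeleton point.
#' @return an `(N + 1) x 2` matrix of `(x, y)` coordinates.
#' @export
angles_to_skeleton <- function(angles, dS = 1, origin = c(0, 0)) {
  if (!is.numeric(dS) || length(dS) != 1 || dS <= 0)
    stop("'dS' must be a positive segment length")
  if (length(angles) < 1) stop("need at least one angle")
  x <- origin[1] + c(0, cumsum(dS * cos(angles)))
  y <- origin[2] + c(0, cumsum(dS * sin(angles)))
  cbind(x = x, y = y)
}

#' Convert skeleton coordinates to tangent angles
#'
#' Inverse of [angles_to_skeleton()]: angle `i` is `atan2(dy_i, dx_i)` of
#' segment `i`, giving `N_S - 1` angles for `N_S` points.
#'
#' @param points matrix of skeleton coordinates, one `(x, y)` row per point.
#' @return numeric vector of tangent angles.
#' @export
skeleton_to_angles <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("a skeleton needs at least 3 points")
  dx <- diff(points[, 1])
  dy <- diff(points[, 2])
  if (any(dx == 0 & dy == 0))
    stop("skeleton contains duplicate consecutive points")
  atan2(dy, dx)
}

#' Mean segment length of a skeleton
#' @param points skeleton coordinate matrix.
#' @return average distance between consecutive points, in pixels.
#' @export
skeleton_ds <- function(points) {
  points <- as.matrix(points)
  mean(sqrt(diff(points[, 1])^2 + diff(points[, 2])^2))
}

#' Root-mean-square angular distance between two centerlines
#'
#' `sqrt(mean(eps_i^2))` where `eps_i` is the wrapped elementwise difference.
#' This is the distance minimized (over head-tail flips) by the network loss.
#'
#' @param c1,c2 angle vectors of equal length.
#' @return distance in radians, `>= 0`, symmetric in its arguments.
#' @export
rmse_angle_distance <- function(c1, c2) {
  if (length(c1) != length(c2)) stop("centerlines differ in length")
  sqrt(mean(wrap_angle_diff(c1, c2)^2))
}

#' Mean absolute angular distance between two centerlines
#'
#' Used by the head-tail assignment step to compare adjacent frames.
#'
#' @inheritParams rmse_angle_distance
#' @return mean of `|eps_i|` in radians.
#' @export
mean_abs_angle_distance <- function(c1, c2) {
  if (length(c1) != length(c2)) stop("centerlines differ in length")
  mean(abs(wrap_angle_diff(c1, c2)))
}

#' Head-tail flip of a centerline
#'
#' Reverses the angle order and rotates each angle by pi, producing the
#' centerline of the same curve traversed tail to head. The operation is an
#' involution: flipping twice returns the original (wrapped) centerline.
#'
#' @param angles angle vector, head to tail.
#' @return flipped angle vector wrapped to `(-pi, pi]`.
#' @export
flip_centerline <- function(angles) {
  wrap_angles(rev(angles) + pi)
}

#' Unwrap a centerline along the body
#'
#' Removes artificial 2*pi jumps between consecutive angles so that linear
#' operations (PCA projections, mixture modeling) see a continuous tangent
#' angle profile. Assumes true per-segment curvature below pi, which holds
#' for any resolvable worm shape.
#'
#' @param angles angle vector.
#' @return continuous angle vector equal to the input modulo elementwise 2*pi.
#' @export
unwrap_body <- function(angles) {
  n <- length(angles)
  if (n < 2) return(angles)
  angles[1] + c(0, cumsum(wrap_angle_diff(angles[-1], angles[-n])))
}

#' Resample a skeleton to a given number of points
#'
#' Arc-length linear interpolation; used whenever a reference and target
#' skeleton disagree on the number of points.
#'
#' @param points skeleton coordinate matrix.
#' @param n_out desired number of points.
#' @return `n_out x 2` coordinate matrix with (approximately) equal spacing.
#' @export
resample_skeleton <- function(points, n_out) {
  points <- as.matrix(points)
  seg <- sqrt(diff(points[, 1])^2 + diff(points[, 2])^2)
  s <- c(0, cumsum(seg))
  target <- seq(0, s[length(s)], length.out = n_out)
  cbind(x = stats::approx(s, points[, 1], xout = target)$y,
        y = stats::approx(s, points[, 2], xout = target)$y)
}

# ---- eigenworm basis --------------------------------------------------------

#' Principal-component basis of worm postures ("eigenworms")
#'
#' Fits a mean-subtracted PCA to a library of centerline angle vectors. The
#' first two components capture the traveling body wave; the third captures
#' the overall turning amplitude, whose projection `a_3` indexes omega- and
#' delta-turns.
#'
#' @param shapes matrix with one angle vector per row (continuous along the
#'   body; see [unwrap_body()]).
#' @param d number of components to keep (default 5).
#' @param source free-text provenance tag stored with the basis.
#' @return an object of class `worm_eigenbasis` with elements `mean`
#'   (length-N vector), `components` (N x d orthonormal matrix),
#'   `var_explained` (fraction per component) and `source`.
#' @export
compute_eigenbasis <- function(shapes, d = 5, source = "unspecified") {
  shapes <- as.matrix(shapes)
  if (nrow(shapes) < d) stop("need at least 'd' shapes")
  pc <- stats::prcomp(shapes, center = TRUE, scale. = FALSE)
  if (d > ncol(pc$rotation)) stop("'d' exceeds the rank of the shape library")
  structure(list(
    mean = as.numeric(pc$center),
    components = pc$rotation[, seq_len(d), drop = FALSE],
    var_explained = pc$sdev[seq_len(d)]^2 / sum(pc$sdev^2),
    source = source
  ), class = "worm_eigenbasis")
}

#' @export
print.worm_eigenbasis <- function(x, ...) {
  cat("Eigenworm basis:", length(x$mean), "angles,",
      ncol(x$components), "components\n")
  cat("  variance explained:",
      paste(sprintf("%.3f", x$var_explained), collapse = " "), "\n")
  cat("  source:", x$source, "\n")
  invisible(x)
}

#' Project centerlines onto an eigenworm basis
#'
#' @param x a single angle vector or a matrix with one angle vector per row.
#' @param basis a `worm_eigenbasis`.
#' @return mode coefficients `a = t(components) %*% (x - mean)`: a vector for
#'   a single centerline, otherwise a matrix with one row per centerline.
#' @export
project_modes <- function(x, basis) {
  if (is.matrix(x)) {
    if (ncol(x) != length(basis$mean)) stop("dimension mismatch with basis")
    sweep(x, 2, basis$mean) %*% basis$components
  } else {
    if (length(x) != length(basis$mean)) stop("dimension mismatch with basis")
    as.numeric(crossprod(basis$components, x - basis$mean))
  }
}

#' Reconstruct a centerline from mode coefficients
#' @param a mode coefficient vector (length `<= d`).
#' @param basis a `worm_eigenbasis`.
#' @return reconstructed angle vector `mean + components %*% a`.
#' @export
reconstruct_from_modes <- function(a, basis) {
  d <- length(a)
  as.numeric(basis$mean + basis$components[, seq_len(d), drop = FALSE] %*% a)
}
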