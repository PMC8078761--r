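# Posture-scale roaming/dwelling analysis: centroid kinematics at 3 Hz,
# a two-state HMM on 10 s windowed speed and angular speed, movement
# directionality relative to the body axis, body-wave phase dynamics in
# eigenworm coordinates, and turning-mode statistics.

#' Centroid kinematics at 3 Hz
#'
#' Downsamples the centroid track to (approximately) 3 Hz, computes the
#' finite-difference velocity `v(t) = (c(t + dt) - c(t)) / dt`, the speed
#' `s = |v|`, and the angular speed as the angle between the two vectors
#' defined by three subsequent centroid points divided by `dt`. Ten-second
#' non-overlapping boxcar means of both series are appended for the
#' roaming/dwelling segmentation.
#'
#' @param centroid `T x 2` matrix of centroid coordinates (pixels, or
#'   physical units when calibrated).
#' @param fps recording frame rate in Hz (must be at least 3).
#' @param target_hz downsampling rate (default 3).
#' @param window_s averaging window in seconds (default 10).
#' @return object of class `kinematics_series`: `time`, `centroid`,
#'   `speed`, `angular_speed`, per-window means `speed_w`/`angspeed_w`
#'   with `window_time`, the downsampling `indices` into the original
#'   series, and `dt`.
#' @export
centroid_kinematics <- function(centroid, fps, target_hz = 3,
                                window_s = 10) {
  if (fps < target_hz) stop("'fps' must be at least ", target_hz, " Hz")
  centroid <- as.matrix(centroid)
  k <- max(1L, round(fps / target_hz))
  idx <- seq(1, nrow(centroid), by = k)
  c3 <- centroid[idx, , drop = FALSE]
  dt <- k / fps
  if (nrow(c3) < window_s / dt + 2)
    stop("series shorter than one averaging window")
  v <- diff(c3) / dt
  speed <- sqrt(rowSums(v^2))                      # length T3 - 1
  heading <- atan2(v[, 2], v[, 1])
  angular_speed <- c(abs(wrap_angle_diff(heading[-1],
                                         heading[-length(heading)])) / dt,
                     NA)                           # aligned with speed
  time <- (idx[-length(idx)] - 1) / fps
  wlen <- round(window_s / dt)
  nw <- floor(length(speed) / wlen)
  wid <- rep(seq_len(nw), each = wlen)
  use <- seq_len(nw * wlen)
  speed_w <- tapply(speed[use], wid, mean, na.rm = TRUE)
  angspeed_w <- tapply(angular_speed[use], wid, mean, na.rm = TRUE)
  structure(list(time = time, centroid = c3[-nrow(c3), , drop = FALSE],
                 speed = speed, angular_speed = angular_speed,
                 window_time = (seq_len(nw) - 0.5) * window_s,
                 speed_w = as.numeric(speed_w),
                 angspeed_w = as.numeric(angspeed_w),
                 indices = idx[-length(idx)], dt = dt),
            class = "kinematics_series")
}

#' @export
print.kinematics_series <- function(x, ...) {
  cat(sprintf(paste0("Kinematics: %d samples at %.2f Hz, %d windows; ",
                     "median speed %.2f px/s\n"),
              length(x$speed), 1 / x$dt, length(x$speed_w),
              stats::median(x$speed, na.rm = TRUE)))
  invisible(x)
}

#' Segment roaming and dwelling states
#'
#' Fits a two-state hidden Markov model with Gaussian emissions (diagonal
#' covariance) to the 10 s windowed speed and angular speed, decodes the
#' state path by Viterbi, and labels the state with the larger mean speed
#' as roaming (high speed, low angular speed) and the other as dwelling.
#'
#' @param kin a [centroid_kinematics()] result.
#' @param seed integer seed for the HMM initialization.
#' @return object of class `roam_dwell`: `states` (factor per window,
#'   levels `dwell`, `roam`), `transition` (row-stochastic, ordered
#'   dwell/roam), `stationary`, `emission` (means and variances per state)
#'   and the underlying `hmm` fit.
#' @export
fit_roam_dwell <- function(kin, seed = 1) {
  stopifnot(inherits(kin, "kinematics_series"))
  X <- cbind(speed = kin$speed_w, angspeed = kin$angspeed_w)
  fit <- gaussian_hmm(X, n_states = 2, seed = seed)
  roam_raw <- which.max(fit$means[, 1])   # canonical: roaming = faster state
  ord <- c(setdiff(1:2, roam_raw), roam_raw)  # dwell first, roam second
  P <- fit$transition[ord, ord]
  states <- factor(ifelse(fit$states == roam_raw, "roam", "dwell"),
                   levels = c("dwell", "roam"))
  structure(list(states = states, transition = P,
                 stationary = stationary_distribution(P),
                 emission = list(means = fit$means[ord, , drop = FALSE],
                                 vars = fit$vars[ord, , drop = FALSE]),
                 hmm = fit),
            class = "roam_dwell")
}

#' @export
print.roam_dwell <- function(x, ...) {
  tab <- table(x$states)
  cat(sprintf("Roaming/dwelling HMM: %d windows (%.1f%% roaming)\n",
              length(x$states), 100 * mean(x$states == "roam")))
  cat("  transition matrix (dwell, roam):\n")
  print(round(x$transition, 3))
  invisible(x)
}

#' Movement direction relative to the body axis
#'
#' `psi = atan2(v_y, v_x)` is the centroid heading, `Psi` the overall
#' tail-to-head angle (mean of the centerline angles); their difference
#' `dpsi = psi - Psi`, normalized into `[-pi/2, 3*pi/2)`, is close to 0 for
#' forward and to pi for backward locomotion. Frames without measurable
#' velocity are masked.
#'
#' @param kin a [centroid_kinematics()] result.
#' @param angle_series full-rate matrix of centerline angles (one frame per
#'   row; sampled at the original `fps`).
#' @param min_speed velocities below this are masked (units of `speed`).
#' @return data frame with `time`, `dpsi` and `forward`
#'   (`dpsi < pi/2`).
#' @export
direction_angle <- function(kin, angle_series, min_speed = 1e-8) {
  stopifnot(inherits(kin, "kinematics_series"))
  angle_series <- as.matrix(angle_series)
  v <- diff(rbind(kin$centroid, NA)) / kin$dt  # same as in kinematics
  v <- v[seq_along(kin$speed), , drop = FALSE]
  psi <- atan2(v[, 2], v[, 1])
  Psi <- rowMeans(angle_series[kin$indices, , drop = FALSE])
  dpsi <- psi - Psi
  dpsi <- ((dpsi + pi / 2) %% (2 * pi)) - pi / 2   # into [-pi/2, 3pi/2)
  dpsi[kin$speed < min_speed] <- NA
  data.frame(time = kin$time, dpsi = dpsi, forward = dpsi < pi / 2)
}

#' Body-wave phase and phase velocity
#'
#' The first two eigenworm projections rotate around the origin as the body
#' wave travels; their quadrant-aware angle `phi = atan2(a2, a1)` (the
#' notational inverse-tangent convention differs between sources, so the
#' sign is configurable) is the wave phase. `phi` is unwrapped over time
#' and the phase velocity `omega` is the derivative of a cubic-spline fit.
#'
#' @param a1,a2 first and second eigenworm projection time series.
#' @param fps sampling rate in Hz.
#' @param phi_sign `+1` (default) for `atan2(a2, a1)`, `-1` for the
#'   opposite convention (flips the forward/backward labeling of `omega`).
#' @param min_amplitude frames with `sqrt(a1^2 + a2^2)` below this are
#'   masked.
#' @return list with `time`, `phi` (unwrapped radians) and `omega` (rad/s).
#' @export
phase_velocity <- function(a1, a2, fps, phi_sign = 1,
                           min_amplitude = 1e-8) {
  stopifnot(length(a1) == length(a2))
  phi_raw <- phi_sign * atan2(a2, a1)
  n <- length(phi_raw)
  phi <- phi_raw[1] + c(0, cumsum(wrap_angle_diff(phi_raw[-1],
                                                  phi_raw[-n])))
  mask <- sqrt(a1^2 + a2^2) < min_amplitude
  t <- (seq_len(n) - 1) / fps
  f <- stats::splinefun(t, phi, method = "fmm")
  omega <- f(t, deriv = 1)
  phi[mask] <- NA; omega[mask] <- NA
  list(time = t, phi = phi, omega = omega)
}

# local maxima with topographic prominence (scipy-style definition)
find_peaks <- function(x, prominence = 0, min_distance = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  cand <- cand[!is.na(x[cand])]
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(p) {
    h <- x[p]
    lmin <- h; i <- p
    while (i > 1 && x[i] <= h) { i <- i - 1; lmin <- min(lmin, x[i]) }
    rmin <- h; i <- p
    while (i < n && x[i] <= h) { i <- i + 1; rmin <- min(rmin, x[i]) }
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= prominence]
  if (length(keep) <= 1 || min_distance <= 1) return(keep)
  # enforce minimum separation, keeping the higher peak
  ord <- keep[order(-x[keep])]
  sel <- logical(n)
  chosen <- integer(0)
  for (p in ord) {
    if (!any(abs(chosen - p) < min_distance)) chosen <- c(chosen, p)
  }
  sort(chosen)
}

#' Count complete body waves
#'
#' Splits the series into maximal runs over which the phase velocity does
#' not change sign, then counts peaks of `cos(phi)` (recurrences of the
#' wave) with prominence 1.95 and a minimum separation of 8 frames within
#' each run. Events are attributed to forward or backward waves by the sign
#' of `omega` in their run.
#'
#' @param phi unwrapped phase series (radians).
#' @param omega phase-velocity series (rad/s), aligned with `phi`.
#' @param fps sampling rate in Hz.
#' @param prominence peak prominence for `cos(phi)` (default 1.95, i.e.
#'   nearly the full -1 to 1 swing).
#' @param min_sep_frames minimum frames between counted peaks (default 8).
#' @return list with `events` (data frame: `frame`, `direction`), counts
#'   `n_forward`/`n_backward`, and `rate` in events per second.
#' @export
count_body_waves <- function(phi, omega, fps, prominence = 1.95,
                             min_sep_frames = 8) {
  stopifnot(length(phi) == length(omega))
  n <- length(phi)
  sgn <- sign(omega)
  sgn[is.na(sgn)] <- 0
  r <- rle(as.integer(sgn))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  events <- data.frame(frame = integer(0), direction = character(0))
  for (k in seq_along(r$lengths)) {
    if (r$values[k] == 0) next
    seg <- starts[k]:ends[k]
    if (length(seg) < 3) next
    pk <- find_peaks(cos(phi[seg]), prominence = prominence,
                     min_distance = min_sep_frames)
    if (length(pk))
      events <- rbind(events, data.frame(
        frame = seg[pk],
        direction = if (r$values[k] > 0) "forward" else "backward"))
  }
  list(events = events,
       n_forward = sum(events$direction == "forward"),
       n_backward = sum(events$direction == "backward"),
       rate = nrow(events) / (n / fps))
}

#' Turning-mode distribution by behavioral state
#'
#' Per-state probability density of the third eigenworm projection `a_3`
#' (turning mode), with the fraction of frames in the omega-turn band
#' (`10 <= |a_3| < 20`) and the delta-turn band (`|a_3| >= 20`).
#'
#' @param a3 turning-mode time series.
#' @param states factor of state labels aligned with `a3`.
#' @param omega_band,delta_min band edges in eigenworm units.
#' @return list per state: `density` (from [stats::density()], `NULL` for
#'   degenerate input), `omega_fraction`, `delta_fraction`, `n`.
#' @export
turn_distribution <- function(a3, states, omega_band = c(10, 20),
                              delta_min = 20) {
  stopifnot(length(a3) == length(states))
  out <- lapply(split(a3, states), function(x) {
    x <- x[!is.na(x)]
    list(density = if (length(x) > 1 && stats::sd(x) > 0)
           stats::density(x) else NULL,
         omega_fraction = mean(abs(x) >= omega_band[1] &
                               abs(x) < omega_band[2]),
         delta_fraction = mean(abs(x) >= delta_min),
         n = length(x))
  })
  class(out) <- "turn_distribution"
  out
}
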