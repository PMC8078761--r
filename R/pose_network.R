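# Residual convolutional regressor from worm image to centerline angles,
# trained with the head-tail-symmetric angular loss. The network itself is
# implemented in compiled code; this file provides the user-facing model
# object, training loop and prediction interface.

#' Network architecture specification
#'
#' A compact residual network: a 7x7, stride-2 convolution stem followed by
#' 2x2 max pooling, then three stages of pre-activation basic blocks with a
#' leaky-rectifier activation, global average pooling and a dense output of
#' `n_out` angles. The default matches images of side 128; the
#' `reduced = TRUE` preset (side 48, half-width stages, two blocks per
#' stage) is sized for CPU-scale experiments on procedural fixtures.
#'
#' @param input_side input image side in pixels (minimum 32; sides below
#'   about 90 px make fine posture detail hard to resolve on real data).
#' @param stage_filters filter counts of the three residual stages.
#' @param blocks_per_stage basic blocks per stage.
#' @param n_out output dimension (number of tangent angles).
#' @param stem_pool logical; max-pool after the stem convolution. The
#'   default follows the input side: pooling suits 128-px inputs, while
#'   small inputs keep more spatial resolution without it.
#' @param reduced logical; use the scaled-down preset.
#' @return list of class `network_spec`.
#' @export
network_spec <- function(input_side = 128, stage_filters = c(32, 64, 128),
                         blocks_per_stage = 3, n_out = 100,
                         stem_pool = input_side >= 96,
                         reduced = FALSE) {
  if (reduced) {
    input_side <- 48; stage_filters <- c(16, 32, 64); blocks_per_stage <- 2
    stem_pool <- TRUE
  }
  if (input_side < 32) stop("the minimum image size is 32 x 32 pixels")
  if (input_side %/% 4 < 2^(length(stage_filters) - 1))
    stop("input side incompatible with the downsampling chain")
  structure(list(input_side = as.integer(input_side),
                 stage_filters = as.integer(stage_filters),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 n_out = as.integer(n_out), stem_pool = stem_pool),
            class = "network_spec")
}

#' Build a pose-regression network
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for the (He) weight initialization; identical
#'   seeds give identical initial networks.
#' @return object of class `pose_network`.
#' @export
build_pose_network <- function(spec = network_spec(), seed = 1) {
  net <- structure(list(spec = spec, seed = as.integer(seed),
                        state = NULL, history = NULL,
                        env = new.env(parent = emptyenv())),
                   class = "pose_network")
  .net_ptr(net)
  net
}

# (re)materialize the compiled network behind a pose_network object
.net_ptr <- function(net) {
  p <- net$env$ptr
  if (is.null(p) || !cpp_xptr_valid(p)) {
    p <- cpp_net_create(net$spec$input_side, net$spec$stage_filters,
                        net$spec$blocks_per_stage, net$spec$n_out,
                        isTRUE(net$spec$stem_pool), net$seed)
    if (!is.null(net$state)) cpp_net_set_state(p, net$state)
    net$env$ptr <- p
  }
  p
}

#' @export
print.pose_network <- function(x, ...) {
  cat(sprintf(
    "Pose network: input %dx%d -> %d angles, stages (%s) x %d blocks\n",
    x$spec$input_side, x$spec$input_side, x$spec$n_out,
    paste(x$spec$stage_filters, collapse = ", "), x$spec$blocks_per_stage))
  cat(sprintf("  %s parameters, %s\n",
              format(cpp_net_num_params(.net_ptr(x)), big.mark = ","),
              if (is.null(x$history)) "untrained" else
                sprintf("trained %d epochs (best eval loss %.4f rad)",
                        nrow(x$history), min(x$history$eval_loss))))
  invisible(x)
}

#' Head-tail-symmetric training loss
#'
#' The distance between a predicted centerline and a label is the minimum
#' of the root-mean-square wrapped angle error to the label and to its
#' head-tail flip, making the loss invariant to which end is called the
#' head -- by construction
#' `symmetric_loss(x, a) == symmetric_loss(flip_centerline(x), a) ==
#' symmetric_loss(x, flip_centerline(a))`.
#'
#' @param theta_hat predicted angle vector.
#' @param theta_a label angle vector (same length).
#' @return scalar loss in radians.
#' @export
symmetric_loss <- function(theta_hat, theta_a) {
  if (length(theta_hat) != length(theta_a))
    stop("centerlines differ in length")
  min(rmse_angle_distance(theta_hat, theta_a),
      rmse_angle_distance(theta_hat, flip_centerline(theta_a)))
}

#' Training configuration
#'
#' @param batch minibatch size (default 128).
#' @param epochs training epochs (default 100).
#' @param lr Adam learning rate (default 0.001).
#' @param lr_final learning rate of the last epoch; when it differs from
#'   `lr` the rate decays geometrically across epochs (short training
#'   budgets benefit from finishing at a lower rate).
#' @param squared_objective descend the squared angular distance instead
#'   of its square root (identical minimizer and head-tail branch choice;
#'   larger gradients on large errors speed up short trainings). Reported
#'   losses are always the root-mean-square distance in radians.
#' @param ema_decay Polyak weight-averaging decay per step (0 disables);
#'   the evaluated and returned checkpoints use the averaged weights,
#'   which stabilizes short noisy trainings.
#' @param seed integer seed for shuffling.
#' @param eval_batch batch size used when evaluating.
#' @param verbose print per-epoch losses.
#' @return list of class `train_config`.
#' @export
train_config <- function(batch = 128, epochs = 100, lr = 0.001,
                         lr_final = lr, squared_objective = FALSE,
                         ema_decay = 0.999, seed = 1, eval_batch = 256,
                         verbose = FALSE) {
  stopifnot(batch >= 1, epochs >= 1, lr > 0, lr_final > 0,
            ema_decay >= 0, ema_decay < 1)
  structure(list(batch = as.integer(batch), epochs = as.integer(epochs),
                 lr = lr, lr_final = lr_final,
                 squared_objective = isTRUE(squared_objective),
                 ema_decay = ema_decay, seed = as.integer(seed),
                 eval_batch = as.integer(eval_batch), verbose = verbose),
            class = "train_config")
}

# per-image normalization: mean-centered pixels (the mean is dominated by
# the uniform background, so this removes background-level variation)
.normalize_images <- function(images) {
  if (length(dim(images)) == 2) images <- array(images, c(dim(images), 1))
  mu <- apply(images, 3, mean)
  sweep(images, 3, mu)
}

.eval_loss <- function(ptr, images, targets, eval_batch) {
  n <- dim(images)[3]
  losses <- numeric(0); sizes <- integer(0)
  for (s in seq(1, n, by = eval_batch)) {
    idx <- s:min(s + eval_batch - 1, n)
    losses <- c(losses, cpp_net_eval_loss(
      ptr, as.numeric(images[, , idx, drop = FALSE]),
      t(targets[idx, , drop = FALSE]), length(idx)))
    sizes <- c(sizes, length(idx))
  }
  sum(losses * sizes) / sum(sizes)
}

#' Train the pose network
#'
#' Minimizes the batch-averaged [symmetric_loss()] with Adam. After every
#' epoch the network is scored on the evaluation set and the checkpoint
#' with the smallest evaluation loss is kept (and restored into the
#' returned model).
#'
#' @param net a `pose_network`.
#' @param train_images `L x L x n` array of training images in `[0, 1]`.
#' @param train_targets `n x n_out` matrix of angle labels.
#' @param eval_images,eval_targets held-out evaluation set (real labeled
#'   frames when available, otherwise fixture frames with known angles).
#' @param config a [train_config()].
#' @return the trained `pose_network` with a `history` data frame
#'   (`epoch`, `train_loss`, `eval_loss`) and the best checkpoint in
#'   `state`.
#' @export
train_pose_network <- function(net, train_images, train_targets,
                               eval_images, eval_targets,
                               config = train_config()) {
  stopifnot(inherits(net, "pose_network"))
  ptr <- .net_ptr(net)
  train_images <- .normalize_images(train_images)
  eval_images <- .normalize_images(eval_images)
  n <- dim(train_images)[3]
  stopifnot(n == nrow(train_targets))
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        eval_loss = numeric(0))
  best <- list(loss = Inf, state = NULL)
  lr_final <- config$lr_final %||% config$lr
  decay <- if (config$epochs > 1)
    (lr_final / config$lr)^(1 / (config$epochs - 1)) else 1
  for (ep in seq_len(config$epochs)) {
    lr_ep <- config$lr * decay^(ep - 1)
    ord <- withr::with_seed(config$seed + ep, sample.int(n))
    batch_losses <- numeric(0)
    for (s in seq(1, n, by = config$batch)) {
      idx <- ord[s:min(s + config$batch - 1, n)]
      loss <- cpp_net_train_batch(
        ptr, as.numeric(train_images[, , idx, drop = FALSE]),
        t(train_targets[idx, , drop = FALSE]), length(idx), lr_ep,
        config$squared_objective, config$ema_decay %||% 0)
      if (!is.finite(loss))
        stop(sprintf(paste0(
          "training diverged (non-finite loss) at epoch %d, step %d; ",
          "try a lower learning rate"), ep, s %/% config$batch + 1))
      batch_losses <- c(batch_losses, loss)
    }
    use_ema <- (config$ema_decay %||% 0) > 0
    if (use_ema) cpp_net_swap_ema(ptr)
    ev <- .eval_loss(ptr, eval_images, eval_targets, config$eval_batch)
    history <- rbind(history, data.frame(
      epoch = ep, train_loss = mean(batch_losses), eval_loss = ev))
    if (ev < best$loss) best <- list(loss = ev, state = cpp_net_get_state(ptr))
    if (use_ema) cpp_net_swap_ema(ptr)  # restore live weights
    if (config$verbose)
      message(sprintf("epoch %3d  train %.4f  eval %.4f rad",
                      ep, mean(batch_losses), ev))
  }
  cpp_net_set_state(ptr, best$state)
  net$state <- best$state
  net$history <- history
  net
}

#' Predict centerline pairs for a set of frames
#'
#' Runs the network on standardized frames and returns, for every frame,
#' the predicted centerline together with its head-tail flip (the flipped
#' member is derived from the prediction, not re-inferred). Frames whose
#' side differs from the network input are resized with a warning.
#'
#' @param net a trained `pose_network`.
#' @param frames list of `processed_frame` objects, or an `L x L x n` array.
#' @param batch prediction batch size.
#' @return list of prediction pairs: each element has `theta`,
#'   `theta_flipped` and `frame_index`.
#' @export
predict_centerlines <- function(net, frames, batch = 256) {
  stopifnot(inherits(net, "pose_network"))
  ptr <- .net_ptr(net)
  side <- net$spec$input_side
  if (is.list(frames))
    imgs <- vapply(frames, function(f) f$image, matrix(0, nrow(frames[[1]]$image), ncol(frames[[1]]$image)))
  else imgs <- frames
  if (length(dim(imgs)) == 2) imgs <- array(imgs, c(dim(imgs), 1))
  if (dim(imgs)[1] != side) {
    warning(sprintf("resizing frames from %d to the network input side %d",
                    dim(imgs)[1], side))
    imgs <- vapply(seq_len(dim(imgs)[3]), function(i)
      matrix(as.numeric(EBImage::resize(EBImage::Image(imgs[, , i]),
                                        w = side, h = side)), side, side),
      matrix(0, side, side))
    imgs <- array(imgs, c(side, side, dim(imgs)[3]))
  }
  imgs <- .normalize_images(imgs)
  n <- dim(imgs)[3]
  out <- vector("list", n)
  for (s in seq(1, n, by = batch)) {
    idx <- s:min(s + batch - 1, n)
    Y <- cpp_net_forward(ptr, as.numeric(imgs[, , idx, drop = FALSE]),
                         length(idx), FALSE)
    for (j in seq_along(idx)) {
      theta <- Y[, j]
      out[[idx[j]]] <- list(theta = theta,
                            theta_flipped = flip_centerline(theta),
                            frame_index = idx[j])
    }
  }
  out
}

#' Save / load a pose network
#'
#' Checkpoints store the architecture, seed, weights and training history
#' in one serialized archive; the compiled network is rebuilt on load.
#'
#' @param net a `pose_network`.
#' @param path file path.
#' @export
save_pose_network <- function(net, path) {
  stopifnot(inherits(net, "pose_network"))
  ptr <- .net_ptr(net)
  saveRDS(list(spec = net$spec, seed = net$seed,
               state = cpp_net_get_state(ptr), history = net$history,
               schema_version = 1L), path)
  invisible(path)
}

#' @rdname save_pose_network
#' @export
load_pose_network <- function(path) {
  x <- readRDS(path)
  if (is.null(x$schema_version)) stop("not a serialized pose network")
  net <- structure(list(spec = x$spec, seed = x$seed, state = x$state,
                        history = x$history,
                        env = new.env(parent = emptyenv())),
                   class = "pose_network")
  .net_ptr(net)
  net
}
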