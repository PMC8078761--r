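# Quantitative benchmarks on procedural fixtures. These run the package
# end to end at a reduced scale and report the same quantities used to
# characterize pose-estimation quality: eigenworm mode errors on held-out
# synthetic images (overall and for coiled shapes), renderer
# self-reconstruction errors, and head-tail orientation accuracy.

#' Eigenworm mode error of the trained network on held-out synthetic images
#'
#' Full scaled-down protocol: generate procedural fixture references, fit
#' the shape mixture to a coil-balanced fixture corpus, render synthetic
#' training images, train the reduced residual network with the symmetric
#' loss, render a held-out synthetic evaluation set, predict, and project
#' predicted and true centerlines onto the fixture eigenbasis. The
#' per-image mode error takes the head-tail orientation minimizing the
#' angular distance to the truth.
#'
#' @param seed master seed; every stage derives its randomness from it.
#' @param n_train,n_eval training and held-out evaluation set sizes.
#' @param epochs training epochs.
#' @param image_size canvas side in pixels.
#' @param n_components mixture components for the scaled corpus.
#' @param corpus_n shape-corpus size.
#' @param n_refs number of rendering templates.
#' @param stage_filters residual-stage widths of the reduced network.
#' @param batch,lr training schedule.
#' @param lr_final,ema_decay learning-rate decay target and Polyak
#'   averaging decay (see [train_config()]).
#' @param coiled_a3 threshold defining the coiled subset (truth `a_3`
#'   above this).
#' @param verbose print training progress.
#' @return list with `median_da1` (median `|delta a_1|` overall),
#'   `median_da1_coiled` (same over the coiled subset), `median_da`
#'   (per-mode medians), `n_eval`, `n_coiled`, `history`, `net`, `basis`.
#' @export
mode_error_benchmark <- function(seed = 1, n_train = 20000, n_eval = 2000,
                                 epochs = 10, image_size = 48,
                                 n_components = 24, corpus_n = 5000,
                                 n_refs = 12, stage_filters = c(24, 48, 96),
                                 batch = 64, lr = 0.003,
                                 lr_final = 0.0003, ema_decay = 0.99,
                                 coiled_a3 = 15, verbose = FALSE) {
  world <- fixture_world(L = image_size, seed = seed)
  video <- generate_fixture_video(world)
  refs <- fixture_reference_frames(video, n = n_refs, seed = seed + 1)
  corpus <- fixture_corpus(world, n = corpus_n, seed = seed + 2)
  sm <- fit_shape_model(corpus, n_components = n_components,
                        seed = seed + 3)
  basis <- fixture_eigenbasis(world, seed = seed + 4)

  training <- generate_training_set(refs, sm, n_train, synth_params(),
                                    seed = seed + 5)
  heldout <- generate_training_set(refs, sm, n_eval, synth_params(),
                                   seed = seed + 6)

  spec <- network_spec(input_side = image_size,
                       stage_filters = stage_filters, blocks_per_stage = 2,
                       stem_pool = TRUE)
  net <- build_pose_network(spec, seed = seed + 7)
  net <- train_pose_network(net, training$images, training$targets,
                            heldout$images, heldout$targets,
                            train_config(batch = batch, epochs = epochs,
                                         lr = lr, lr_final = lr_final,
                                         ema_decay = ema_decay,
                                         seed = seed + 8,
                                         verbose = verbose))

  preds <- predict_centerlines(net, heldout$images)
  n <- length(preds)
  d <- ncol(basis$components)
  da <- matrix(NA_real_, n, d)
  a3_true <- numeric(n)
  for (i in seq_len(n)) {
    truth <- heldout$targets[i, ]
    cand <- preds[[i]]$theta
    if (rmse_angle_distance(cand, truth) >
        rmse_angle_distance(preds[[i]]$theta_flipped, truth))
      cand <- preds[[i]]$theta_flipped
    # mode error = projection of the wrapped angular error field, so that
    # the comparison is between poses, not 2*pi branch representatives
    err <- wrap_angle_diff(cand, truth)
    da[i, ] <- abs(crossprod(basis$components, err))
    # truth turning mode, with the sampled global rotation removed
    a3_true[i] <- project_modes(truth - heldout$meta$rotation[i],
                                basis)[3]
  }
  coiled <- a3_true > coiled_a3
  list(median_da1 = stats::median(da[, 1]),
       median_da1_coiled = stats::median(da[coiled, 1]),
       median_da = apply(da, 2, stats::median),
       median_da_coiled = apply(da[coiled, , drop = FALSE], 2,
                                stats::median),
       n_eval = n, n_coiled = sum(coiled),
       history = net$history, net = net, basis = basis)
}

#' Renderer self-reconstruction errors on fixture references
#'
#' Renders each reference frame's own labeled centerline (augmentations
#' off) and scores it against the reference image with the image error; a
#' faithful renderer gives errors far below the 0.3 discard threshold.
#' Intensity-inverted originals are scored as well: the error uses the
#' absolute correlation, so a perfectly anti-correlated reconstruction is
#' also an excellent match.
#'
#' @param n_refs number of reference frames.
#' @param seed integer seed for the fixture world.
#' @return list with `errors`, `errors_inverted` and `n`.
#' @export
reconstruction_error_benchmark <- function(n_refs = 200, seed = 1) {
  world <- fixture_world(L = 48, duration_s = 60, coil_rate_hz = 0.02,
                         seed = seed)
  video <- generate_fixture_video(world)
  refs <- fixture_reference_frames(video, n = n_refs, seed = seed + 1)
  angles <- lapply(refs, function(r)
    unwrap_body(skeleton_to_angles(r$skeleton)))
  errors <- vapply(seq_along(refs), function(i)
    image_error(refs[[i]]$processed, angles[[i]], refs[[i]])$error,
    numeric(1))
  errors_inverted <- vapply(seq_along(refs), function(i) {
    inv <- refs[[i]]$processed
    inv$image <- 1 - inv$image
    image_error(inv, angles[[i]], refs[[i]])$error
  }, numeric(1))
  list(errors = errors, errors_inverted = errors_inverted,
       n = length(refs))
}

#' Head-tail orientation accuracy on a fixture video
#'
#' Builds temporally consistent segments from (ground-truth-plus-noise)
#' prediction pairs with randomized head assignment, orients them with the
#' labeled non-coiled frames, and reports the fraction of retained frames
#' whose final head-tail orientation matches the ground truth.
#'
#' @param n_frames video length in frames.
#' @param noise_sd angular noise added to the simulated predictions.
#' @param seed integer seed.
#' @return list with `accuracy`, `n_retained`, `n_frames` and the
#'   `oriented` segments.
#' @export
orientation_accuracy_benchmark <- function(n_frames = 2000,
                                           noise_sd = 0.05, seed = 1) {
  world <- fixture_world(L = 48, fps = 30, duration_s = n_frames / 30,
                         seed = seed)
  video <- generate_fixture_video(world)
  truth <- video$truth
  pairs <- simulate_predictions(truth, sd = noise_sd, seed = seed + 1)
  segments <- build_segments(pairs, video$fps, seed = seed + 2)
  lab <- which(video$labeled)
  oriented <- orient_segments(segments, lab,
                              truth[lab, , drop = FALSE])
  correct <- 0L; total <- 0L
  for (s in oriented) {
    for (j in seq_along(s$frames)) {
      th <- s$angles[j, ]; tr <- truth[s$frames[j], ]
      total <- total + 1L
      if (rmse_angle_distance(th, tr) <=
          rmse_angle_distance(th, flip_centerline(tr)))
        correct <- correct + 1L
    }
  }
  list(accuracy = correct / total, n_retained = total,
       n_frames = n_frames, oriented = oriented)
}
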