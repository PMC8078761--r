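# Dataset-adapter API and pipeline orchestration. The adapter is the only
# path through which the pipeline touches data, so procedural fixtures and
# user recordings are interchangeable; stages cache their artifacts under a
# run directory and are resumable.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a dataset adapter
#'
#' An adapter bundles indexed frame access with the per-frame labels of a
#' classical tracker (centerline coordinates head to tail, three body
#' widths, frame rate) and the dataset-specific preprocessing hook.
#'
#' @param n_frames number of frames.
#' @param get_frame function(i) returning the raw grayscale frame matrix.
#' @param fps frame rate in Hz.
#' @param labeled_frames integer vector of labeled frame indices (a subset
#'   of all frames).
#' @param get_features function(i) returning, for a labeled frame, a list
#'   with `skeleton` (coordinates in the raw frame) and `widths3`.
#' @param preprocess optional function(raw) overriding [segment_worm()].
#' @param name adapter name.
#' @return list of class `dataset_adapter`.
#' @export
dataset_adapter <- function(n_frames, get_frame, fps, labeled_frames,
                            get_features, preprocess = NULL,
                            name = "custom") {
  stopifnot(fps > 0, is.function(get_frame), is.function(get_features))
  if (length(labeled_frames) &&
      (min(labeled_frames) < 1 || max(labeled_frames) > n_frames))
    stop("labeled frames must be a subset of the frame indices")
  structure(list(n_frames = as.integer(n_frames), get_frame = get_frame,
                 fps = fps, labeled_frames = as.integer(labeled_frames),
                 get_features = get_features, preprocess = preprocess,
                 name = name),
            class = "dataset_adapter")
}

#' Adapter over a procedural fixture video
#' @param video a `fixture_video`.
#' @return a [dataset_adapter()].
#' @export
fixture_adapter <- function(video) {
  stopifnot(inherits(video, "fixture_video"))
  dataset_adapter(
    n_frames = dim(video$frames)[3],
    get_frame = function(i) video$frames[, , i],
    fps = video$fps,
    labeled_frames = which(video$labeled),
    get_features = function(i) list(skeleton = video$skeletons[[i]],
                                    widths3 = video$widths3),
    name = "fixture")
}

# ---- plugin registry --------------------------------------------------------

.adapter_registry <- new.env(parent = emptyenv())

#' Register / retrieve dataset-adapter factories
#'
#' A light plugin mechanism: packages or analysis scripts can register a
#' factory under a name, and pipelines can look adapters up by that name.
#'
#' @param name adapter name.
#' @param factory function returning a [dataset_adapter()].
#' @export
register_dataset_adapter <- function(name, factory) {
  stopifnot(is.function(factory))
  assign(name, factory, envir = .adapter_registry)
  invisible(name)
}

#' @rdname register_dataset_adapter
#' @export
get_dataset_adapter <- function(name) {
  if (!exists(name, envir = .adapter_registry))
    stop("no dataset adapter registered under '", name, "'; available: ",
         paste(ls(.adapter_registry), collapse = ", "))
  get(name, envir = .adapter_registry)
}

#' @rdname register_dataset_adapter
#' @export
list_dataset_adapters <- function() ls(.adapter_registry)

# ---- pipeline ---------------------------------------------------------------

#' Pipeline configuration
#'
#' Defaults follow the full-scale protocol (500k synthetic training images,
#' 100 epochs, 270 mixture components); scale them down together with the
#' dataset for desk-scale runs.
#'
#' @param image_size processed-frame side; `NULL` derives it from the
#'   labeled worm lengths.
#' @param n_components mixture components for the shape model.
#' @param n_train synthetic training images.
#' @param epochs,batch,lr training schedule.
#' @param network a [network_spec()] or `NULL` to derive one from
#'   `image_size`.
#' @param n_refs number of reference frames used as rendering templates.
#' @param error_threshold image-error discard threshold.
#' @param max_gap interpolation gap limit (frames).
#' @param smooth apply Savitzky-Golay smoothing to the final series.
#' @param extra_shapes optional matrix of additional (e.g. coiled) centered
#'   angle vectors appended to the shape-model corpus.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(image_size = NULL, n_components = 270,
                            n_train = 500000, epochs = 100, batch = 128,
                            lr = 0.001, network = NULL, n_refs = 12,
                            error_threshold = 0.3, max_gap = 4,
                            smooth = TRUE, extra_shapes = NULL, seed = 1) {
  structure(list(image_size = image_size, n_components = n_components,
                 n_train = n_train, epochs = epochs, batch = batch, lr = lr,
                 network = network, n_refs = n_refs,
                 error_threshold = error_threshold, max_gap = max_gap,
                 smooth = smooth, extra_shapes = extra_shapes,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage_cache <- function(run_dir, name, config_digest, compute) {
  f <- file.path(run_dir, paste0(name, ".rds"))
  if (file.exists(f)) {
    x <- readRDS(f)
    if (identical(x$digest, config_digest)) return(x$value)
  }
  value <- compute()
  saveRDS(list(digest = config_digest, value = value), f)
  value
}

# angles (head to tail) of a labeled skeleton in processed-frame pixels,
# resampled to n_points
.feature_angles <- function(features, offset, n_points) {
  skel <- sweep(as.matrix(features$skeleton), 2, offset)
  skel <- resample_skeleton(skel, n_points)
  unwrap_body(skeleton_to_angles(skel))
}

#' Run the full pose-estimation pipeline
#'
#' Orchestrates preprocessing, shape-model fitting, synthetic training-set
#' generation, network training, prediction and temporal post-processing.
#' Stage artifacts are cached under `run_dir` (keyed by the configuration),
#' so an interrupted run resumes and a rerun with identical configuration
#' reuses every stage.
#'
#' @param adapter a [dataset_adapter()].
#' @param config a [pipeline_config()].
#' @param run_dir directory for cached artifacts and results.
#' @param model optional pre-trained `pose_network`; skips synthesis and
#'   training.
#' @param verbose print stage progress.
#' @return list of class `pipeline_result`: `results` (per-frame data
#'   frame: frame, time, image error, orientation source, discarded),
#'   `angles` (per-frame centerline matrix with `NA` gaps), `model`,
#'   `shape_model`, `basis`, `threshold`, `config`.
#' @export
run_pipeline <- function(adapter, config = pipeline_config(), run_dir,
                         model = NULL, verbose = FALSE) {
  stopifnot(inherits(adapter, "dataset_adapter"))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  digest <- paste(deparse(config[setdiff(names(config), "extra_shapes")]),
                  collapse = "")
  say <- function(...) if (verbose) message(sprintf(...))
  n_out <- 100L
  seed <- config$seed

  say("stage 1/6: preprocessing %d frames", adapter$n_frames)
  lab <- adapter$labeled_frames
  lengths <- vapply(lab, function(i) {
    s <- as.matrix(adapter$get_features(i)$skeleton)
    sum(sqrt(diff(s[, 1])^2 + diff(s[, 2])^2))
  }, numeric(1))
  L <- config$image_size %||% default_frame_size(lengths)
  processed <- .stage_cache(run_dir, "processed", digest, function() {
    lapply(seq_len(adapter$n_frames), function(i)
      process_frame(adapter$get_frame(i), L = L))
  })
  usable <- !vapply(processed, is.null, logical(1))

  say("stage 2/6: shape model (%d components)", config$n_components)
  lab_ok <- lab[usable[lab]]
  label_angles <- t(vapply(lab_ok, function(i)
    .feature_angles(adapter$get_features(i), processed[[i]]$offset,
                    n_out + 1L), numeric(n_out)))
  corpus <- sweep(label_angles, 1, rowMeans(label_angles))  # remove rotation
  if (!is.null(config$extra_shapes))
    corpus <- rbind(corpus, as.matrix(config$extra_shapes))
  sm <- .stage_cache(run_dir, "shape_model", digest, function()
    fit_shape_model(corpus, n_components = min(config$n_components,
                                               nrow(corpus) %/% 2),
                    seed = seed))
  basis <- compute_eigenbasis(corpus, d = 5,
                              source = paste0(adapter$name, " labeled frames"))

  refs_idx <- lab_ok[unique(round(seq(1, length(lab_ok),
                                      length.out = config$n_refs)))]
  refs <- lapply(refs_idx, function(i) {
    skel <- sweep(as.matrix(adapter$get_features(i)$skeleton), 2,
                  processed[[i]]$offset)
    skel <- resample_skeleton(skel, n_out + 1L)
    skel[] <- pmin(pmax(skel, 1), L)
    reference_frame(processed[[i]],
                    skel, adapter$get_features(i)$widths3)
  })

  if (is.null(model)) {
    say("stage 3/6: rendering %d synthetic images", config$n_train)
    training <- .stage_cache(run_dir, "training_set", digest, function()
      generate_training_set(refs, sm, config$n_train, synth_params(),
                            seed = seed + 1L))
    say("stage 4/6: training (%d epochs)", config$epochs)
    eval_idx <- lab_ok[seq(1, length(lab_ok),
                           length.out = min(length(lab_ok), 10000))]
    eval_imgs <- array(0, c(L, L, length(eval_idx)))
    for (j in seq_along(eval_idx))
      eval_imgs[, , j] <- processed[[eval_idx[j]]]$image
    eval_targets <- t(vapply(eval_idx, function(i)
      .feature_angles(adapter$get_features(i), processed[[i]]$offset,
                      n_out + 1L), numeric(n_out)))
    spec <- config$network %||% network_spec(
      input_side = L, stage_filters = c(16, 32, 64), blocks_per_stage = 2,
      n_out = n_out)
    model <- .stage_cache(run_dir, "model", digest, function()
      train_pose_network(build_pose_network(spec, seed = seed),
                         training$images, training$targets,
                         eval_imgs, eval_targets,
                         train_config(batch = config$batch,
                                      epochs = config$epochs,
                                      lr = config$lr, seed = seed)))
  } else say("stages 3-4/6: skipped (pre-trained model supplied)")

  say("stage 5/6: predicting %d frames", sum(usable))
  pairs <- .stage_cache(run_dir, "predictions", digest, function() {
    out <- vector("list", adapter$n_frames)
    idx <- which(usable)
    imgs <- array(0, c(L, L, length(idx)))
    for (j in seq_along(idx)) imgs[, , j] <- processed[[idx[j]]]$image
    preds <- predict_centerlines(model, imgs)
    for (j in seq_along(idx)) {
      preds[[j]]$frame_index <- idx[j]
      out[[idx[j]]] <- preds[[j]]
    }
    out
  })

  say("stage 6/6: scoring and head-tail resolution")
  post <- .stage_cache(run_dir, "postprocess", digest, function() {
    errors <- rep(NA_real_, adapter$n_frames)
    for (i in which(usable)) {
      ref <- refs[[which.min(abs(refs_idx - i))]]
      ep <- image_error_pair(processed[[i]], pairs[[i]], ref)
      errors[i] <- min(ep$error)
    }
    keep_pairs <- pairs
    for (i in seq_along(keep_pairs))
      if (!usable[i] || is.na(errors[i]) ||
          errors[i] > config$error_threshold) keep_pairs[i] <- list(NULL)
    segments <- build_segments(keep_pairs, adapter$fps, seed = seed)
    oriented <- orient_segments(segments, lab_ok, label_angles)
    series <- segments_to_series(oriented)
    series <- interpolate_gaps(series, max_gap = config$max_gap)
    list(errors = errors, oriented = oriented, series = series)
  })
  series <- post$series
  covered <- !is.na(series[, 1])
  if (config$smooth && sum(covered) > 9) {
    runs <- rle(covered)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
    for (k in seq_along(runs$lengths))
      if (runs$values[k] && runs$lengths[k] > 9)
        series[starts[k]:ends[k], ] <-
          smooth_angles(series[starts[k]:ends[k], , drop = FALSE])
  }
  source_by_frame <- rep(NA_character_, adapter$n_frames)
  for (s in post$oriented) source_by_frame[s$frames] <- s$orientation_source

  results <- data.frame(
    frame = seq_len(adapter$n_frames),
    time = (seq_len(adapter$n_frames) - 1) / adapter$fps,
    image_error = post$errors,
    orientation_source = source_by_frame,
    discarded = !covered)
  out <- list(results = results, angles = series, model = model,
              shape_model = sm, basis = basis,
              threshold = config$error_threshold, config = config,
              image_side = L)
  class(out) <- "pipeline_result"
  saveRDS(out, file.path(run_dir, "result.rds"))
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d frames, %.1f%% resolved (threshold %.2f)\n",
              nrow(x$results), 100 * mean(!x$results$discarded),
              x$threshold))
  invisible(x)
}

#' Export a per-frame result series to WCON
#'
#' Writes the minimal Worm tracker Commons Object Notation subset: time,
#' per-point `x`/`y` skeleton coordinates (head first) and units, so that
#' results interoperate with other worm-tracking tools.
#'
#' @param result a `pipeline_result` (or an angle matrix).
#' @param path output file.
#' @param fps frame rate (taken from the results when available).
#' @param dS skeleton segment length in pixels.
#' @param id track identifier.
#' @return the path, invisibly.
#' @export
export_wcon <- function(result, path, fps = NULL, dS = 1, id = "worm1") {
  if (inherits(result, "pipeline_result")) {
    angles <- result$angles
    t <- result$results$time
  } else {
    angles <- as.matrix(result)
    if (is.null(fps)) stop("'fps' is required for a plain angle matrix")
    t <- (seq_len(nrow(angles)) - 1) / fps
  }
  keep <- !is.na(angles[, 1])
  pts <- lapply(which(keep), function(i)
    angles_to_skeleton(angles[i, ], dS = dS))
  obj <- list(
    units = list(t = "s", x = "pixel", y = "pixel"),
    metadata = list(who = "nemapose"),
    data = list(list(
      id = id, t = t[keep],
      x = lapply(pts, function(p) round(p[, 1], 3)),
      y = lapply(pts, function(p) round(p[, 2], 3)),
      head = "first")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
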