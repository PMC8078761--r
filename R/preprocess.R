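# Frame standardization: segment the worm, uniformize the background and
# produce square worm-centered images of a fixed side. Morphology, blurring
# and thresholding are delegated to EBImage.

#' Segment the worm in a raw grayscale frame
#'
#' Gaussian blur (5 px window), automatic Otsu threshold, morphological
#' closing, connected components; the component search is restricted to the
#' central region of the frame (15% cropped per side) and the largest blob
#' is kept. The background value is the mean of the non-foreground pixels of
#' the original image.
#'
#' @param raw numeric matrix (rows = y, columns = x) with values in `[0, 1]`.
#' @param dark_worm logical; `TRUE` (default) when the worm is darker than
#'   the background.
#' @return list with `mask` (logical matrix), `background_value`, and
#'   `usable` (`FALSE` when no foreground object was found).
#' @export
segment_worm <- function(raw, dark_worm = TRUE) {
  raw <- as.matrix(raw)
  blurred <- cpp_gauss_blur(raw, 1.1)  # sigma matching a 5-px kernel window
  rng <- range(blurred)
  if (diff(rng) < 1e-8)
    return(list(mask = NULL, background_value = mean(raw), usable = FALSE))
  thr <- EBImage::otsu(EBImage::Image(blurred), range = rng)
  fg <- if (dark_worm) blurred < thr else blurred > thr
  fg <- EBImage::closing(fg, EBImage::makeBrush(3, shape = "box")) > 0
  if (!any(fg))
    return(list(mask = NULL, background_value = mean(raw), usable = FALSE))
  background_value <- mean(raw[!fg])
  # label blobs, then keep the largest blob present in the central region
  labels <- EBImage::bwlabel(EBImage::Image(fg * 1))
  labels <- matrix(as.integer(labels), nrow(raw), ncol(raw))
  my <- round(0.15 * nrow(raw)); mx <- round(0.15 * ncol(raw))
  central <- labels[(my + 1):(nrow(raw) - my), (mx + 1):(ncol(raw) - mx)]
  ids <- central[central > 0]
  if (length(ids) == 0)
    return(list(mask = NULL, background_value = background_value,
                usable = FALSE))
  best <- as.integer(names(which.max(table(ids))))
  list(mask = labels == best, background_value = background_value,
       usable = TRUE)
}

#' Standardize a segmented frame to a square worm-centered image
#'
#' Crops or pads the raw frame to an `L x L` window centered on the worm
#' blob centroid and sets every non-worm pixel to the background value, so
#' that processed real frames and synthetic renderings share the same
#' appearance. When `capture_side` differs from `L` the window is resized
#' with linear interpolation.
#'
#' @param raw numeric matrix in `[0, 1]`.
#' @param mask logical worm mask from [segment_worm()].
#' @param background_value gray level for non-worm pixels.
#' @param L output side in pixels (minimum 32).
#' @param capture_side side of the window cut from the raw frame before
#'   resizing; defaults to `L` (no resize).
#' @return an object of class `processed_frame`: `image`, `worm_mask`,
#'   `background_value`, `offset` (x, y of the window origin in the raw
#'   frame, 0-based) and `L`.
#' @export
standardize_frame <- function(raw, mask, background_value, L,
                              capture_side = L) {
  if (L < 32) stop("the minimum image size is 32 x 32 pixels")
  raw <- as.matrix(raw)
  if (is.null(mask) || !any(mask)) stop("empty worm mask")
  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  side <- capture_side
  bh <- diff(range(idx[, 1])) + 1; bw <- diff(range(idx[, 2])) + 1
  if (bh > side || bw > side)
    stop("worm bounding box exceeds the capture window; increase 'L' or ",
         "set 'capture_side' to at least ", max(bh, bw),
         " and let the frame be resized")
  y0 <- round(cy) - side %/% 2; x0 <- round(cx) - side %/% 2
  img <- matrix(background_value, side, side)
  msk <- matrix(FALSE, side, side)
  ys <- pmax(1, y0 + 1):pmin(nrow(raw), y0 + side)
  xs <- pmax(1, x0 + 1):pmin(ncol(raw), x0 + side)
  img[ys - y0, xs - x0] <- raw[ys, xs]
  msk[ys - y0, xs - x0] <- mask[ys, xs]
  img[!msk] <- background_value
  if (side != L) {
    img <- matrix(as.numeric(
      EBImage::resize(EBImage::Image(img), w = L, h = L)), L, L)
    msk <- matrix(as.numeric(
      EBImage::resize(EBImage::Image(msk * 1), w = L, h = L)), L, L) > 0.5
    img[!msk] <- background_value
  }
  structure(list(image = img, worm_mask = msk,
                 background_value = background_value,
                 offset = c(x = x0, y = y0), L = L),
            class = "processed_frame")
}

#' @export
print.processed_frame <- function(x, ...) {
  cat(sprintf("Processed frame %dx%d, background %.3f, worm area %d px\n",
              x$L, x$L, x$background_value, sum(x$worm_mask)))
  invisible(x)
}

#' Segment and standardize a raw frame in one step
#' @inheritParams segment_worm
#' @inheritParams standardize_frame
#' @return a `processed_frame`, or `NULL` when the frame is unusable.
#' @export
process_frame <- function(raw, L, dark_worm = TRUE, capture_side = L) {
  seg <- segment_worm(raw, dark_worm = dark_worm)
  if (!seg$usable) return(NULL)
  standardize_frame(raw, seg$mask, seg$background_value, L,
                    capture_side = capture_side)
}

#' Default processed-image side for a dataset
#'
#' The recommended processed-image side is the average worm length of the
#' biggest worm in the dataset, which is large enough to contain any posture
#' of that worm; lengths are measured from the labeled skeletons.
#'
#' @param skeleton_lengths numeric vector of per-frame worm lengths in
#'   pixels (one entry per labeled frame, possibly several worms pooled).
#' @param worm_id optional factor identifying the worm for each entry.
#' @return integer image side (at least 32).
#' @export
default_frame_size <- function(skeleton_lengths, worm_id = NULL) {
  if (is.null(worm_id)) size <- mean(skeleton_lengths)
  else size <- max(tapply(skeleton_lengths, worm_id, mean))
  max(32L, as.integer(ceiling(size)))
}

#' Read a folder of grayscale images as a frame list
#'
#' @param path directory containing image files (PNG or TIFF), read in
#'   lexicographic order.
#' @return list of numeric matrices in `[0, 1]`.
#' @export
read_image_folder <- function(path) {
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) stop("no image files found in ", path)
  lapply(files, function(f) {
    img <- EBImage::readImage(f)
    if (length(dim(img)) == 3) img <- EBImage::channel(img, "luminance")
    # EBImage stores x as the first dimension; transpose to rows = y
    t(as.matrix(img))
  })
}
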