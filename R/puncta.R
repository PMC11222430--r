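#' Crop a sub-stack around a cluster along the myotube axis
#'
#' Extracts a window of the stated physical length (default 40 um) along the
#' myotube axis, centered on the cluster centroid; the window is clamped at
#' the stack borders with a warning.
#'
#' @param stack a \code{\link{calibrated_image}} z-stack or 3-D array.
#' @param centroid_px cluster centroid, \code{c(y, x, z)} in pixels (1-based).
#' @param length_um crop length (default 40).
#' @param axis myotube axis, \code{"x"} (default) or \code{"y"}.
#' @param pixel_size_um required for bare arrays.
#' @return for calibrated images, a cropped \code{calibrated_image}; for
#'   arrays, the cropped array. The crop range is attached as attribute
#'   \code{"crop_range"}.
#' @export
crop_around_cluster <- function(stack, centroid_px, length_um = 40,
                                axis = c("x", "y"), pixel_size_um = NULL) {
  axis <- match.arg(axis)
  is_ci <- inherits(stack, "calibrated_image")
  ps <- if (is_ci) stack$pixel_size else pixel_size_um
  stopifnot(!is.null(ps), length_um > 0)
  d <- if (is_ci) dim(stack$data)[1:2] else dim(stack)[1:2]
  n_ax <- if (axis == "x") d[2] else d[1]
  ctr <- if (axis == "x") centroid_px[2] else centroid_px[1]
  if (ctr < 1 || ctr > n_ax) stop("centroid outside stack")
  half <- round(length_um / ps / 2)
  lo <- round(ctr) - half
  hi <- round(ctr) + half
  if (lo < 1 || hi > n_ax) {
    warning("crop clamped at stack border")
    lo <- max(1, lo)
    hi <- min(n_ax, hi)
  }
  rng <- lo:hi
  if (is_ci) {
    out <- stack
    out$data <- if (axis == "x") stack$data[, rng, , , , drop = FALSE]
                else stack$data[rng, , , , , drop = FALSE]
  } else {
    out <- if (axis == "x") stack[, rng, , drop = FALSE]
           else stack[rng, , , drop = FALSE]
  }
  attr(out, "crop_range") <- c(lo, hi)
  out
}

#' Segment myotube volume from the surface-label channel
#'
#' Reproducible surrogate for contrast-based manual outlining: contrast
#' stretch, global Otsu threshold to pick up the labelled surface outline,
#' largest 3-D connected component, then hole filling across the tube
#' cross-sections (Y-Z planes, the planes in which a tube cut is an annulus)
#' to recover the enclosed volume. A manual mask can be passed through
#' untouched via \code{manual_mask}.
#'
#' @param stack a \code{\link{calibrated_image}} or (Y, X, Z) array.
#' @param channel channel holding the surface label (default
#'   \code{"new_label"} when present, else the first channel).
#' @param manual_mask optional 3-D logical mask that overrides segmentation.
#' @param pixel_size_um,z_step_um calibration for bare arrays.
#' @return list with \code{mask} (3-D logical) and \code{volume_um3}.
#' @export
segment_myotube_volume <- function(stack, channel = NULL, manual_mask = NULL,
                                   pixel_size_um = NULL, z_step_um = NULL) {
  if (inherits(stack, "calibrated_image")) {
    ps <- stack$pixel_size
    zs <- stack$z_step
    if (is.null(channel))
      channel <- if ("new_label" %in% stack$channels) "new_label"
                 else stack$channels[1]
    x <- get_channel(stack, channel)
  } else {
    stopifnot(!is.null(pixel_size_um), !is.null(z_step_um))
    ps <- pixel_size_um
    zs <- z_step_um
    x <- stack
  }
  voxvol <- ps^2 * zs
  if (!is.null(manual_mask))
    return(list(mask = manual_mask, volume_um3 = sum(manual_mask) * voxvol))
  # saturated contrast stretch: clipping the extremes keeps the rare, very
  # bright surface cluster from dominating the threshold
  r <- stats::quantile(x, c(0.005, 0.995), names = FALSE)
  if (r[1] == r[2]) stop("no foreground found in the myotube channel")
  xs <- pmin(pmax((x - r[1]) / (r[2] - r[1]), 0), 1)
  dim(xs) <- dim(x)
  mask <- xs > otsu_threshold(xs)
  if (!any(mask)) stop("no foreground found in the myotube channel")
  lab <- label_components_3d(mask)
  sz <- tabulate(lab[lab > 0])
  shell <- lab == which.max(sz)
  filled <- shell
  for (x_i in seq_len(dim(shell)[2])) {
    sl <- shell[, x_i, ]
    if (any(sl)) filled[, x_i, ] <- EBImage::fillHull(sl) > 0
  }
  list(mask = filled, volume_um3 = sum(filled) * voxvol)
}

#' Detect endocytic puncta in the old-label channel
#'
#' Scale-space blob surrogate for manual counting: Gaussian smoothing at the
#' punctum scale, 26-neighbourhood local maxima restricted to the myotube
#' mask, excluding the surface-cluster zone (the cluster mask dilated by
#' \code{exclude_um}), and thresholded at \code{k} robust SDs above the
#' in-mask background. Deterministic for fixed parameters. Manual counts can
#' be imported instead with [read_region_table()] and [puncta_density()].
#'
#' @param stack a \code{\link{calibrated_image}} or (Y, X, Z) array
#'   (old-label channel).
#' @param mask 3-D logical myotube mask.
#' @param cluster_mask optional 3-D logical surface-cluster mask to exclude.
#' @param exclude_um dilation of the exclusion zone in micrometres
#'   (default 0.5).
#' @param sigma_um smoothing scale (default 0.25).
#' @param k detection threshold in robust background SDs (default 5).
#' @param channel channel for calibrated images (default
#'   \code{"old_label"} when present).
#' @param pixel_size_um,z_step_um calibration for bare arrays.
#' @return list with \code{coords} (n x 3 matrix, y/x/z px) and \code{count}.
#' @export
detect_puncta <- function(stack, mask, cluster_mask = NULL, exclude_um = 0.5,
                          sigma_um = 0.25, k = 5, channel = NULL,
                          pixel_size_um = NULL, z_step_um = NULL) {
  if (inherits(stack, "calibrated_image")) {
    ps <- stack$pixel_size
    zs <- stack$z_step
    if (is.null(channel))
      channel <- if ("old_label" %in% stack$channels) "old_label"
                 else stack$channels[1]
    x <- get_channel(stack, channel)
  } else {
    stopifnot(!is.null(pixel_size_um), !is.null(z_step_um))
    ps <- pixel_size_um
    zs <- z_step_um
    x <- stack
  }
  stopifnot(identical(dim(x), dim(mask)))
  search <- mask
  if (!is.null(cluster_mask)) {
    excl <- cluster_mask
    for (i in seq_len(max(1, round(exclude_um / ps))))
      excl <- dilate_ball1_3d(excl)
    search <- search & !excl
  }
  xs <- gaussian_smooth_3d(x, sigma_px = max(sigma_um / ps, 0.5),
                           sigma_z = max(sigma_um / zs, 0.3))
  bgv <- xs[search]
  if (length(bgv) == 0) return(list(coords = matrix(numeric(0), 0, 3), count = 0L))
  thr <- stats::median(bgv) + k * stats::mad(bgv)
  cand <- xs > thr & search & local_max_3d(xs)
  # edge padding correlates the smoothed noise; maxima on the outermost
  # planes are unreliable and are excluded
  mgn <- max(2L, ceiling(2 * sigma_um / ps))
  d3 <- dim(cand)
  cand[c(seq_len(mgn), d3[1] - seq_len(mgn) + 1L), , ] <- FALSE
  cand[, c(seq_len(mgn), d3[2] - seq_len(mgn) + 1L), ] <- FALSE
  cand[, , c(1L, d3[3])] <- FALSE
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) > 1) {
    # merge maxima closer than the punctum scale (plateaux split by noise),
    # keeping the brightest of each group
    vals <- xs[cand]
    ord <- order(-vals)
    idx <- idx[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(idx))
    min_sep <- max(2, round(0.5 / ps))
    for (i in seq_len(nrow(idx))) {
      if (!keep[i]) next
      if (i < nrow(idx)) {
        later <- (i + 1):nrow(idx)
        d2 <- (idx[later, 1] - idx[i, 1])^2 + (idx[later, 2] - idx[i, 2])^2 +
              ((idx[later, 3] - idx[i, 3]) * zs / ps)^2
        keep[later][d2 < min_sep^2] <- FALSE
      }
    }
    idx <- idx[keep, , drop = FALSE]
  }
  list(coords = idx, count = nrow(idx))
}

#' Puncta density per muscle volume
#'
#' @param count puncta count.
#' @param volume_um3 myotube volume in cubic micrometres (> 0).
#' @return puncta per 1000 um^3.
#' @export
#' @examples
#' puncta_density(5, 2500)  # 2
puncta_density <- function(count, volume_um3) {
  stopifnot(count >= 0)
  if (volume_um3 <= 0) stop("puncta density undefined for zero volume")
  1000 * count / volume_um3
}

#' Parameters of the presynaptic-marker label pipeline
#'
#' @param opening_radius 3-D opening radius in voxels (default 1).
#' @param dilation_radius 3-D dilation radius in voxels (default 1).
#' @param size_window inclusive keep-range of component voxel counts
#'   (default \code{c(1000, 115000)}).
#' @param final_dilation_radius 2-D per-slice dilation radius in pixels
#'   (default 2).
#' @return an object of class \code{label_pipeline_params}.
#' @export
label_pipeline_params <- function(opening_radius = 1, dilation_radius = 1,
                                  size_window = c(1000, 115000),
                                  final_dilation_radius = 2) {
  stopifnot(opening_radius >= 0, dilation_radius >= 0,
            final_dilation_radius >= 0, length(size_window) == 2,
            size_window[1] <= size_window[2])
  structure(list(opening_radius = opening_radius,
                 dilation_radius = dilation_radius,
                 size_window = size_window,
                 final_dilation_radius = final_dilation_radius),
            class = "label_pipeline_params")
}

#' Volumetric label filtering for presynaptic marker signal
#'
#' The cleanup pipeline for vesicular-transporter (vAChT) stacks, in order:
#' Otsu binarization; 3-D morphological opening then dilation (ball
#' structuring elements in voxel units); 3-D connected-components labeling;
#' size filtering keeping components whose voxel count lies inside the
#' inclusive window; a further per-slice 2-D dilation; Otsu re-threshold of
#' the label volume into a binary mask; and zeroing of all signal outside
#' that mask.
#'
#' @param stack 3-D numeric array (or \code{\link{calibrated_image}}; the
#'   first channel is used).
#' @param params a \code{\link{label_pipeline_params}}.
#' @return list with \code{labels} (integer 3-D array, renumbered 1..n),
#'   \code{mask} (3-D logical), \code{masked_signal} (input with outside
#'   voxels zeroed), \code{sizes} (kept component voxel counts).
#' @export
vacht_label_pipeline <- function(stack, params = label_pipeline_params()) {
  if (inherits(stack, "calibrated_image")) stack <- get_channel(stack, 1)
  stopifnot(length(dim(stack)) == 3L, inherits(params, "label_pipeline_params"))
  bw <- stack > otsu_threshold(stack)
  for (i in seq_len(params$opening_radius)) bw <- erode_ball1_3d(bw)
  for (i in seq_len(params$opening_radius)) bw <- dilate_ball1_3d(bw)
  for (i in seq_len(params$dilation_radius)) bw <- dilate_ball1_3d(bw)
  lab <- label_components_3d(bw)
  lab <- filter_components_by_size(lab, params$size_window[1],
                                   params$size_window[2])
  sizes <- tabulate(lab[lab > 0])
  if (params$final_dilation_radius > 0) {
    brush <- EBImage::makeBrush(2 * params$final_dilation_radius + 1, "disc")
    for (z in seq_len(dim(lab)[3]))
      lab[, , z] <- EBImage::imageData(EBImage::dilate(lab[, , z], brush))
  }
  mask <- lab > otsu_threshold(lab)
  if (all(lab == 0)) mask[] <- FALSE
  masked <- stack
  masked[!mask] <- 0
  list(labels = lab, mask = mask, masked_signal = masked, sizes = sizes)
}

#' Keep labeled components by voxel-count window
#'
#' Components with voxel count in \code{[min_voxels, max_voxels]} inclusive
#' are kept and renumbered 1..n in ascending original label order; all
#' others are removed.
#'
#' @param labels integer label array (any dimensionality).
#' @param min_voxels,max_voxels inclusive bounds.
#' @return relabeled integer array.
#' @export
filter_components_by_size <- function(labels, min_voxels, max_voxels) {
  if (max(labels) == 0) return(labels)
  sz <- tabulate(labels[labels > 0])
  keep <- which(sz >= min_voxels & sz <= max_voxels)
  map <- integer(length(sz))
  map[keep] <- seq_along(keep)
  out <- labels
  out[labels > 0] <- map[labels[labels > 0]]
  storage.mode(out) <- "integer"
  out
}
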