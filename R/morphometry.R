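#' Maximum-intensity z-projection
#'
#' Per-pixel maximum over the z axis; lateral calibration and channels are
#' carried over.
#'
#' @param stack a \code{\link{calibrated_image}} with a z axis, or a
#'   (Y, X, Z) array.
#' @return same type as the input, projected to a single plane.
#' @export
project_max_z <- function(stack) {
  if (inherits(stack, "calibrated_image")) {
    d <- dim(stack$data)
    if (d[4] < 1) stop("no z axis")
    out <- array(0, c(d[1], d[2], d[3], 1, d[5]))
    for (ci in seq_len(d[3])) for (t in seq_len(d[5]))
      out[, , ci, 1, t] <- apply(stack$data[, , ci, , t, drop = FALSE], c(1, 2), max)
    return(calibrated_image(out, axes = c("Y", "X", "C", "Z", "T"),
                            pixel_size = stack$pixel_size,
                            frame_interval = stack$frame_interval,
                            channels = stack$channels))
  }
  if (length(dim(stack)) == 2L) return(stack)
  if (length(dim(stack)) != 3L) stop("expected a (Y, X, Z) array")
  apply(stack, c(1, 2), max)
}

#' Sum-intensity z-projection
#'
#' Per-pixel sum over z — the projection the positivity threshold rule is
#' defined on for stack data.
#'
#' @inheritParams project_max_z
#' @return projected array / image.
#' @export
project_sum_z <- function(stack) {
  if (inherits(stack, "calibrated_image")) {
    d <- dim(stack$data)
    out <- array(0, c(d[1], d[2], d[3], 1, d[5]))
    for (ci in seq_len(d[3])) for (t in seq_len(d[5]))
      out[, , ci, 1, t] <- apply(stack$data[, , ci, , t, drop = FALSE], c(1, 2), sum)
    # sums can exceed the 16-bit range; keep as raw array semantics
    img <- calibrated_image(pmin(out, 65535 * d[4]),
                            axes = c("Y", "X", "C", "Z", "T"),
                            pixel_size = stack$pixel_size,
                            frame_interval = stack$frame_interval,
                            channels = stack$channels)
    return(img)
  }
  if (length(dim(stack)) == 2L) return(stack)
  apply(stack, c(1, 2), sum)
}

#' Segment a single receptor cluster in a cropped ROI
#'
#' The crop is assumed to contain one cluster. The default threshold is a
#' global Otsu cut on the crop — the reproducible surrogate for the original
#' manual thresholding — and an explicit \code{threshold} is accepted for
#' parity with a manual workflow. Only the largest connected foreground
#' component is kept.
#'
#' @param crop numeric matrix (cropped max-z projection).
#' @param threshold optional manual threshold; foreground is strictly above.
#' @return logical matrix; empty (with a warning) when nothing is above
#'   threshold or the crop is blank.
#' @export
segment_cluster <- function(crop, threshold = NULL) {
  stopifnot(is.matrix(crop))
  thr <- if (is.null(threshold)) otsu_threshold(crop) else threshold
  mask <- crop > thr
  if (!any(mask)) {
    warning("empty cluster mask: no pixel above threshold")
    return(mask)
  }
  lab <- EBImage::bwlabel(mask)
  sz <- tabulate(lab[lab > 0])
  lab == which.max(sz)
}

#' Measure cluster shape parameters
#'
#' Area (pixel count times pixel area), perimeter (chain-code corrected
#' boundary estimator), perimeter/area, and solidity (area over rasterized
#' convex-hull area) of a single-cluster mask. See [label_regions()] for the
#' estimator conventions.
#'
#' @param mask logical matrix with one non-empty cluster.
#' @param pixel_size_um pixel size in micrometres.
#' @param en_face optional flag carried into the result (see
#'   [flag_en_face()]).
#' @return one-row data frame: \code{area_um2}, \code{perimeter_um},
#'   \code{perimeter_over_area_per_um}, \code{solidity}, \code{en_face}.
#' @export
measure_cluster <- function(mask, pixel_size_um, en_face = NA) {
  stopifnot(is.matrix(mask), pixel_size_um > 0)
  if (!any(mask)) stop("empty mask")
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- 1L
  tab <- measure_regions(lab, NULL, pixel_size_um)
  data.frame(area_um2 = tab$area_um2, perimeter_um = tab$perimeter_um,
             perimeter_over_area_per_um = tab$perimeter_um / tab$area_um2,
             solidity = tab$solidity, en_face = en_face)
}

#' Flag en-face clusters
#'
#' A cluster viewed face-on has a small axial extent relative to its lateral
#' extent; side-view clusters must be excluded because projection distorts
#' their 2-D shape. The flag is TRUE iff (z-extent in um) / (maximum lateral
#' extent in um) is at most \code{ratio}.
#'
#' @param stack a \code{\link{calibrated_image}} z-stack or a (Y, X, Z)
#'   array (then \code{pixel_size_um} and \code{z_step_um} are required).
#' @param mask logical matrix (cluster footprint in the projection).
#' @param ratio acceptance bound on z/lateral extent (default 0.5).
#' @param frac intensity fraction defining the cluster's z-extent: planes
#'   whose in-footprint mean exceeds background + \code{frac} of the dynamic
#'   range count as occupied (default 0.5).
#' @param channel channel for multi-channel stacks (default first).
#' @param pixel_size_um,z_step_um calibration for bare arrays.
#' @return logical.
#' @export
flag_en_face <- function(stack, mask, ratio = 0.5, frac = 0.5, channel = NULL,
                         pixel_size_um = NULL, z_step_um = NULL) {
  if (inherits(stack, "calibrated_image")) {
    ps <- stack$pixel_size
    zs <- stack$z_step
    x <- get_channel(stack, if (is.null(channel)) stack$channels[1] else channel)
  } else {
    stopifnot(!is.null(pixel_size_um), !is.null(z_step_um))
    ps <- pixel_size_um
    zs <- z_step_um
    x <- stack
  }
  if (length(dim(x)) != 3L) stop("expected a z-stack")
  stopifnot(any(mask))
  prof <- vapply(seq_len(dim(x)[3]), function(z) mean(x[, , z][mask]), numeric(1))
  lo <- min(prof)
  occ <- prof > lo + frac * (max(prof) - lo)
  z_extent <- if (any(occ)) (diff(range(which(occ))) + 1) * zs else zs
  idx <- which(mask, arr.ind = TRUE)
  lateral <- max(diff(range(idx[, 1])) + 1, diff(range(idx[, 2])) + 1) * ps
  (z_extent / lateral) <= ratio
}
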