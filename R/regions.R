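#' Labeled regions with per-region measurements
#'
#' Couples an integer instance map with a measurement table. Geometry is
#' reported in physical units (micrometres) using the image calibration.
#'
#' Conventions, fixed package-wide:
#' \itemize{
#' \item area = pixel count \eqn{\times} pixel area;
#' \item perimeter from the traced outer contour, chain-code weighted
#'   0.948 per axial and 1.340 per diagonal step (a corner-corrected
#'   estimator whose error on digital disks is below 1\%);
#' \item circularity = \eqn{4\pi A / P^2}, clamped to \[0, 1\];
#' \item solidity = region pixel count / pixel count of the rasterized
#'   convex hull of the region's pixel centers, so any digitally convex
#'   region scores exactly 1;
#' \item centroids are 0-based pixel-center coordinates times pixel size.
#' }
#'
#' @param labels integer matrix; 0 = background, positive = instance id.
#' @param image optional intensity source for per-region means: a matrix, a
#'   named list of matrices, or a \code{\link{calibrated_image}} (all
#'   channels are measured).
#' @param pixel_size lateral pixel size in micrometres.
#' @return An object of class \code{labeled_regions}: list with
#'   \code{labels}, \code{table} (data frame: label, area_um2, perimeter_um,
#'   circularity, solidity, centroid_y_um, centroid_x_um, n_px, and one
#'   \code{mean_<channel>} column per intensity channel), \code{pixel_size}.
#' @export
label_regions <- function(labels, image = NULL, pixel_size) {
  stopifnot(is.matrix(labels), pixel_size > 0)
  labels <- round(labels)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels,
                 table = measure_regions(labels, image, pixel_size),
                 pixel_size = pixel_size),
            class = "labeled_regions")
}

#' @export
print.labeled_regions <- function(x, ...) {
  cat(sprintf("<labeled_regions> %d regions on a %d x %d map (pixel %.4g um)\n",
              nrow(x$table), nrow(x$labels), ncol(x$labels), x$pixel_size))
  invisible(x)
}

#' Number of regions
#' @param regions a \code{labeled_regions} object.
#' @return integer count.
#' @export
n_regions <- function(regions) nrow(regions$table)

#' Measure geometry and intensity of labeled regions
#'
#' @inheritParams label_regions
#' @return data frame, one row per label (see [label_regions()]).
#' @export
measure_regions <- function(labels, image = NULL, pixel_size) {
  ids <- sort(unique(labels[labels > 0]))
  pa <- pixel_size^2
  chans <- list()
  if (!is.null(image)) {
    if (inherits(image, "calibrated_image")) {
      chans <- lapply(image$channels, function(ch) get_channel(image, ch))
      names(chans) <- image$channels
    } else if (is.list(image)) chans <- image
    else chans <- list(intensity = image)
    for (ch in chans) stopifnot(identical(dim(ch)[1:2], dim(labels)))
  }
  if (length(ids) == 0L) {
    tab <- data.frame(label = integer(), area_um2 = numeric(),
                      perimeter_um = numeric(), circularity = numeric(),
                      solidity = numeric(), centroid_y_um = numeric(),
                      centroid_x_um = numeric(), n_px = integer())
    for (nm in names(chans)) tab[[paste0("mean_", nm)]] <- numeric()
    return(tab)
  }
  clab <- if (identical(ids, seq_along(ids))) labels else relabel(labels, ids)
  contours <- EBImage::ocontour(clab)
  idx <- which(labels > 0, arr.ind = TRUE)
  lab_at <- labels[labels > 0]
  n_px <- tabulate(lab_at)[ids]
  cy <- tapply(idx[, 1] - 1, lab_at, mean)[as.character(ids)]
  cx <- tapply(idx[, 2] - 1, lab_at, mean)[as.character(ids)]
  per <- vapply(seq_along(ids),
                function(i) .chain_perimeter(contours[[i]]), numeric(1))
  sol <- vapply(ids, function(i) .hull_solidity(idx[lab_at == i, , drop = FALSE]),
                numeric(1))
  area <- n_px * pa
  circ <- pmin(4 * pi * n_px / per^2, 1)
  tab <- data.frame(label = ids, area_um2 = area, perimeter_um = per * pixel_size,
                    circularity = circ, solidity = sol,
                    centroid_y_um = as.numeric(cy) * pixel_size,
                    centroid_x_um = as.numeric(cx) * pixel_size,
                    n_px = as.integer(n_px))
  for (nm in names(chans)) {
    v <- chans[[nm]][labels > 0]
    tab[[paste0("mean_", nm)]] <-
      as.numeric(tapply(v, lab_at, mean)[as.character(ids)])
  }
  rownames(tab) <- NULL
  tab
}

# chain-code perimeter in pixel units from an ocontour coordinate matrix
.chain_perimeter <- function(pts) {
  if (is.null(pts) || nrow(pts) < 4L) return(0.948 * 4)  # sub-2x2 speck
  d <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
  steps <- abs(d[, 1]) + abs(d[, 2])
  sum(ifelse(steps == 1, 0.948, 1.340))
}

# solidity = n(region px) / n(px whose centers fall in the convex hull of
# region pixel centers); digitally convex regions give exactly 1
.hull_solidity <- function(idx) {
  n <- nrow(idx)
  if (n <= 3L) return(1)
  pts <- cbind(as.numeric(idx[, 1]), as.numeric(idx[, 2]))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]            # clockwise order per ?chull
  if (nrow(hp) <= 2L) return(1)
  n / .count_in_hull(hp)
}

# count integer lattice points inside a convex polygon (either orientation)
.count_in_hull <- function(hp) {
  eps <- 1e-9
  m <- nrow(hp)
  jx <- c(2:m, 1L)
  signed2 <- sum(hp[, 1] * hp[jx, 2] - hp[jx, 1] * hp[, 2])
  ry <- range(hp[, 1]); rx <- range(hp[, 2])
  gy <- seq(ceiling(ry[1] - eps), floor(ry[2] + eps))
  gx <- seq(ceiling(rx[1] - eps), floor(rx[2] + eps))
  py <- rep(gy, times = length(gx))
  px <- rep(gx, each = length(gy))
  inside <- rep(TRUE, length(py))
  for (i in seq_len(m)) {
    j <- jx[i]
    cr <- (hp[j, 1] - hp[i, 1]) * (px - hp[i, 2]) -
          (hp[j, 2] - hp[i, 2]) * (py - hp[i, 1])
    inside <- inside & if (signed2 >= 0) cr >= -eps else cr <= eps
    if (!any(inside)) break
  }
  sum(inside)
}

#' Relabel a label map to consecutive ids
#'
#' @param labels integer label matrix.
#' @param keep ids to retain, in the order they should be renumbered.
#' @return integer matrix with labels \code{seq_along(keep)}.
#' @keywords internal
relabel <- function(labels, keep) {
  map <- integer(max(labels, 1L))
  map[keep] <- seq_along(keep)
  out <- labels
  out[labels > 0] <- map[labels[labels > 0]]
  storage.mode(out) <- "integer"
  out
}
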