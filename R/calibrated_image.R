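#' Calibrated microscopy image
#'
#' A lightweight container pairing pixel data with physical calibration.
#' Data are kept in a fixed canonical dimension order \code{(Y, X, C, Z, T)};
#' constructors and readers permute whatever they are given into this order,
#' so downstream code never has to guess axis meaning. Calibration is in
#' micrometres per pixel laterally, micrometres per z-plane axially, and
#' seconds per frame in time.
#'
#' @param data numeric array; a matrix (Y, X) or an array with dimensions
#'   named by \code{axes}.
#' @param axes character vector naming the dimensions of \code{data} in their
#'   storage order, drawn from \code{c("Y","X","C","Z","T")}. Defaults to
#'   \code{c("Y","X")} for a matrix and \code{c("Y","X","C")} for a 3-D array.
#' @param pixel_size lateral pixel size in micrometres (> 0).
#' @param z_step axial step in micrometres (> 0); required when a Z axis of
#'   length > 1 is present.
#' @param frame_interval frame interval in seconds (> 0); required when a T
#'   axis of length > 1 is present.
#' @param channels character vector of unique channel names, one per C plane.
#'
#' @return An object of class \code{calibrated_image}: a list with elements
#'   \code{data} (5-D array, dims Y, X, C, Z, T), \code{pixel_size},
#'   \code{z_step}, \code{frame_interval}, \code{channels}.
#' @export
#' @examples
#' img <- calibrated_image(matrix(0, 16, 16), pixel_size = 0.28,
#'                         channels = "DAPI")
#' dim(img$data)
calibrated_image <- function(data, axes = NULL, pixel_size, z_step = NA_real_,
                             frame_interval = NA_real_, channels = "ch1") {
  if (!is.numeric(data)) stop("'data' must be numeric")
  if (is.null(dim(data))) dim(data) <- c(length(data), 1L)
  nd <- length(dim(data))
  if (is.null(axes)) {
    axes <- switch(as.character(nd),
                   "2" = c("Y", "X"),
                   "3" = c("Y", "X", "C"),
                   "4" = c("Y", "X", "C", "Z"),
                   "5" = c("Y", "X", "C", "Z", "T"),
                   stop("cannot infer axes for a ", nd, "-D array"))
  }
  axes <- toupper(axes)
  if (length(axes) != nd) stop("'axes' must name every dimension of 'data'")
  if (!all(axes %in% c("Y", "X", "C", "Z", "T")) || anyDuplicated(axes))
    stop("'axes' must be distinct labels among Y, X, C, Z, T")
  full <- c("Y", "X", "C", "Z", "T")
  # expand missing axes as singletons, then permute to canonical order
  for (ax in setdiff(full, axes)) {
    dim(data) <- c(dim(data), 1L)
    axes <- c(axes, ax)
  }
  data <- aperm(data, match(full, axes))
  stopifnot(pixel_size > 0)
  d <- dim(data)
  if (d[4] > 1 && (is.na(z_step) || z_step <= 0))
    stop("a z-stack needs a positive 'z_step'")
  if (d[5] > 1 && (is.na(frame_interval) || frame_interval <= 0))
    stop("a time series needs a positive 'frame_interval'")
  channels <- as.character(channels)
  if (length(channels) != d[3])
    stop("need exactly one channel name per C plane (", d[3], ")")
  if (anyDuplicated(channels)) stop("channel names must be unique")
  structure(list(data = data, pixel_size = pixel_size, z_step = z_step,
                 frame_interval = frame_interval, channels = channels),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<calibrated_image> %d x %d px", d[1], d[2]))
  if (d[4] > 1) cat(sprintf(" x %d z", d[4]))
  if (d[5] > 1) cat(sprintf(" x %d frames", d[5]))
  cat(sprintf("\n  channels: %s\n  pixel %.4g um", paste(x$channels, collapse = ", "),
              x$pixel_size))
  if (!is.na(x$z_step)) cat(sprintf("; z-step %.4g um", x$z_step))
  if (!is.na(x$frame_interval)) cat(sprintf("; frame %.4g s", x$frame_interval))
  cat("\n")
  invisible(x)
}

#' Extract one channel of a calibrated image
#'
#' @param img a \code{\link{calibrated_image}}.
#' @param channel channel name or integer index.
#' @param drop drop singleton Z/T dimensions (default TRUE), yielding a
#'   matrix for single-plane images, a (Y, X, Z) array for z-stacks, and a
#'   (Y, X, T) array for movies.
#' @return numeric array for that channel.
#' @export
get_channel <- function(img, channel, drop = TRUE) {
  stopifnot(inherits(img, "calibrated_image"))
  ci <- if (is.character(channel)) match(channel, img$channels) else as.integer(channel)
  if (is.na(ci) || ci < 1 || ci > length(img$channels))
    stop("unknown channel: ", channel)
  out <- img$data[, , ci, , , drop = FALSE]
  d <- dim(out)
  if (drop) {
    keep <- c(TRUE, TRUE, FALSE, d[4] > 1, d[5] > 1)
    dim(out) <- d[keep]
  }
  out
}

#' Physical pixel area of a calibrated image
#' @param img a \code{\link{calibrated_image}} (or a numeric pixel size).
#' @return pixel area in square micrometres.
#' @export
pixel_area <- function(img) {
  ps <- if (inherits(img, "calibrated_image")) img$pixel_size else img
  ps^2
}

#' Physical voxel volume of a calibrated z-stack
#' @param img a \code{\link{calibrated_image}} with z calibration.
#' @return voxel volume in cubic micrometres.
#' @export
voxel_volume <- function(img) {
  stopifnot(inherits(img, "calibrated_image"), !is.na(img$z_step))
  img$pixel_size^2 * img$z_step
}
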