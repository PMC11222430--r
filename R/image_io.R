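#' Write a calibrated image to TIFF with a JSON calibration sidecar
#'
#' Pixel data are written as a multi-page 16-bit TIFF (pages ordered T-major,
#' then Z, then C), and a JSON sidecar \code{<path>.json} records dimensions,
#' channel names and the physical calibration. Intensities must be integers
#' in \[0, 65535\] (arbitrary units, as produced by a camera or by the
#' synthetic generator); the round trip is then exact.
#'
#' @param img a \code{\link{calibrated_image}}.
#' @param path output file path (conventionally \code{.tif}).
#' @return \code{path}, invisibly.
#' @seealso [read_image()]
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "calibrated_image"))
  x <- img$data
  if (any(x < 0) || any(x > 65535))
    stop("intensities must lie in [0, 65535] AU")
  if (max(abs(x - round(x))) > 1e-8)
    warning("non-integer intensities are rounded to integer AU")
  x <- round(x)
  d <- dim(x)
  pages <- vector("list", d[3] * d[4] * d[5])
  i <- 0L
  for (t in seq_len(d[5])) for (z in seq_len(d[4])) for (ci in seq_len(d[3])) {
    i <- i + 1L
    pages[[i]] <- x[, , ci, z, t] / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "deflate")
  meta <- list(dim = d, axes = c("Y", "X", "C", "Z", "T"),
               page_order = c("T", "Z", "C"),
               channels = img$channels, pixel_size_um = img$pixel_size,
               z_step_um = img$z_step, frame_interval_s = img$frame_interval)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a calibrated image from TIFF
#'
#' Reads TIFF written by [write_image()] (restoring array and calibration
#' exactly from the JSON sidecar), or any plain single/multi-page TIFF when
#' the calibration is supplied via \code{override}. A plain TIFF without
#' sidecar and without overrides is an error: physical calibration is never
#' guessed.
#'
#' @param path TIFF file path.
#' @param override optional named list with any of \code{pixel_size_um},
#'   \code{z_step_um}, \code{frame_interval_s}, \code{channels}, \code{axes}
#'   (for plain TIFF: axis meaning of the page dimension, \code{"C"},
#'   \code{"Z"} or \code{"T"}; default \code{"Z"}). See
#'   [read_calibration_yaml()] to load overrides from a YAML file.
#' @return a \code{\link{calibrated_image}}.
#' @export
read_image <- function(path, override = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # ignore spurious extra samples
    round(p * 65535)
  })
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    d <- as.integer(meta$dim)
    x <- array(0, d)
    i <- 0L
    for (t in seq_len(d[5])) for (z in seq_len(d[4])) for (ci in seq_len(d[3])) {
      i <- i + 1L
      x[, , ci, z, t] <- pages[[i]]
    }
    cal <- list(pixel_size_um = meta$pixel_size_um, z_step_um = meta$z_step_um,
                frame_interval_s = meta$frame_interval_s,
                channels = meta$channels)
    if (!is.null(override)) cal <- modifyList(cal, override)
    return(calibrated_image(x, axes = c("Y", "X", "C", "Z", "T"),
                            pixel_size = cal$pixel_size_um,
                            z_step = if (is.null(cal$z_step_um)) NA_real_ else cal$z_step_um,
                            frame_interval = if (is.null(cal$frame_interval_s)) NA_real_
                                             else cal$frame_interval_s,
                            channels = cal$channels))
  }
  if (is.null(override) || is.null(override$pixel_size_um))
    stop("no calibration sidecar for '", path,
         "' and no pixel_size_um override supplied")
  page_axis <- if (is.null(override$axes)) "Z" else toupper(override$axes)
  stopifnot(page_axis %in% c("C", "Z", "T"))
  x <- simplify2array(pages)                       # (Y, X, pages) or (Y, X)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[3]
  channels <- override$channels
  if (is.null(channels)) channels <- if (page_axis == "C")
    paste0("ch", seq_len(n)) else "ch1"
  calibrated_image(x, axes = c("Y", "X", page_axis),
                   pixel_size = override$pixel_size_um,
                   z_step = if (is.null(override$z_step_um)) NA_real_ else override$z_step_um,
                   frame_interval = if (is.null(override$frame_interval_s)) NA_real_
                                    else override$frame_interval_s,
                   channels = channels)
}

#' Write / read an integer label map as 16-bit TIFF
#'
#' Label maps (instance segmentations) are stored as multi-page 16-bit TIFF;
#' label identities survive the round trip exactly for labels up to 65535.
#'
#' @param labels integer matrix (2-D) or array (3-D, pages = z).
#' @param path file path.
#' @return \code{write_label_map}: \code{path} invisibly;
#'   \code{read_label_map}: the integer label array.
#' @export
write_label_map <- function(labels, path) {
  if (max(labels) > 65535) stop("more than 65535 labels")
  x <- round(labels)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  pages <- lapply(seq_len(dim(x)[3]), function(z) x[, , z] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "deflate")
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  x <- simplify2array(lapply(pages, function(p) round(p * 65535)))
  storage.mode(x) <- "integer"
  if (length(dim(x)) == 3L && dim(x)[3] == 1L) dim(x) <- dim(x)[1:2]
  x
}

#' Write / read a per-region measurement table as CSV
#'
#' Plain CSV with header; numeric values round-trip at full precision
#' (15 significant digits).
#'
#' @param table a data frame of per-region measurements (see
#'   [measure_regions()]).
#' @param path file path.
#' @param comments optional character vector written as leading `#` comment
#'   lines (provenance: software version, parameters).
#' @return \code{write_region_table}: \code{path} invisibly;
#'   \code{read_region_table}: the data frame.
#' @export
write_region_table <- function(table, path, comments = NULL) {
  stopifnot(is.data.frame(table))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  utils::write.csv(format(table, digits = 15, scientific = FALSE, trim = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_region_table
#' @export
read_region_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Load calibration overrides from a YAML file
#'
#' Accepts keys \code{pixel_size_um}, \code{z_step_um},
#' \code{frame_interval_s}, \code{channels}, \code{axes}; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return a named list usable as \code{override} in [read_image()].
#' @export
read_calibration_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("pixel_size_um", "z_step_um", "frame_interval_s", "channels", "axes")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) stop("unknown calibration keys: ", paste(bad, collapse = ", "))
  cfg
}
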