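#' Background model and positivity threshold
#'
#' The positivity rule used throughout the pipeline: measure background in a
#' handful of regions, pool their pixels, and call anything strictly above
#' \eqn{\mu_{bg} + k\,\sigma_{bg}} positive (default \eqn{k = 2}).
#'
#' By default the sampler picks the \code{n_regions} darkest non-overlapping
#' \code{block}-pixel square tiles of the image — a reproducible surrogate
#' for manually chosen background boxes; explicit regions can be supplied
#' instead as a list of \code{(y0, y1, x0, x1)} vectors (1-based, inclusive).
#'
#' @param image numeric matrix (single channel; sum-z-project stacks first).
#' @param k threshold multiplier on the background SD (default 2).
#' @param n_regions number of background regions to sample (default 5).
#' @param block tile side in pixels for the automatic sampler (default 32).
#' @param regions optional explicit region list, bypassing the sampler.
#' @return An object of class \code{background_model}: list with \code{mu},
#'   \code{sigma} (pooled pixel mean/SD over the sampled regions), \code{k},
#'   \code{threshold} = \code{mu + k * sigma}, \code{n_regions},
#'   \code{regions}.
#' @export
#' @examples
#' img <- matrix(10, 64, 64)
#' m <- estimate_background(img)
#' m$threshold  # 10: sigma is 0 on a constant image
estimate_background <- function(image, k = 2, n_regions = 5, block = 32,
                                regions = NULL) {
  stopifnot(is.matrix(image), k > 0, n_regions >= 1)
  if (is.null(regions)) {
    ny <- nrow(image) %/% block
    nx <- ncol(image) %/% block
    if (ny * nx < n_regions) {         # image smaller than the tile grid
      block <- max(4L, min(nrow(image), ncol(image)) %/%
                     ceiling(sqrt(n_regions)))
      ny <- nrow(image) %/% block
      nx <- ncol(image) %/% block
    }
    if (ny * nx < 1) stop("image too small to sample background regions")
    tiles <- expand.grid(ty = seq_len(ny), tx = seq_len(nx))
    means <- mapply(function(ty, tx) {
      mean(image[((ty - 1) * block + 1):(ty * block),
                 ((tx - 1) * block + 1):(tx * block)])
    }, tiles$ty, tiles$tx)
    pick <- order(means)[seq_len(min(n_regions, length(means)))]
    regions <- lapply(pick, function(i) {
      ty <- tiles$ty[i]; tx <- tiles$tx[i]
      c((ty - 1) * block + 1, ty * block, (tx - 1) * block + 1, tx * block)
    })
  }
  if (length(regions) < 1) stop("background sampler yielded no regions")
  px <- unlist(lapply(regions, function(r)
    as.numeric(image[r[1]:r[2], r[3]:r[4]])))
  mu <- mean(px)
  sigma <- if (length(px) > 1) stats::sd(px) else 0
  structure(list(mu = mu, sigma = sigma, k = k,
                 threshold = mu + k * sigma,
                 n_regions = length(regions), regions = regions),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> mu = %.4g, sigma = %.4g, k = %g, threshold = %.4g (%d regions)\n",
              x$mu, x$sigma, x$k, x$threshold, x$n_regions))
  invisible(x)
}

#' Threshold an image against a background model
#'
#' A pixel is positive iff strictly greater than the model threshold
#' \eqn{\mu_{bg} + k\,\sigma_{bg}}.
#'
#' @param image numeric matrix.
#' @param model a \code{\link{estimate_background}} model (or a single
#'   numeric threshold).
#' @return logical matrix.
#' @export
threshold_positive_mask <- function(image, model) {
  thr <- if (inherits(model, "background_model")) model$threshold else model
  image > thr
}

#' Debris filter specification
#'
#' Regions are deleted when they look like cell debris: area below
#' \code{min_area_um2} \emph{and} circularity inside \code{circ_window}
#' (default \[0.3, 1\]). Because the conjunctive reading of that rule is not
#' the only possible one, \code{mode = "area_only"} deletes on area alone.
#'
#' @param min_area_um2 minimum area in square micrometres (default 500).
#' @param circ_window circularity interval (default \code{c(0.3, 1.0)}).
#' @param mode \code{"conjunction"} (default) or \code{"area_only"}.
#' @return an object of class \code{debris_filter}.
#' @export
debris_filter <- function(min_area_um2 = 500, circ_window = c(0.3, 1.0),
                          mode = c("conjunction", "area_only")) {
  mode <- match.arg(mode)
  stopifnot(min_area_um2 > 0, length(circ_window) == 2,
            circ_window[1] <= circ_window[2],
            circ_window[1] >= 0, circ_window[2] <= 1)
  structure(list(min_area_um2 = min_area_um2, circ_window = circ_window,
                 mode = mode), class = "debris_filter")
}

#' Remove debris-like regions
#'
#' @param regions a \code{\link{label_regions}} object whose table carries
#'   \code{area_um2} and \code{circularity}.
#' @param filter a \code{\link{debris_filter}}.
#' @return a \code{labeled_regions} object with surviving regions relabeled
#'   1..n in their original order.
#' @export
filter_debris <- function(regions, filter = debris_filter()) {
  stopifnot(inherits(regions, "labeled_regions"), inherits(filter, "debris_filter"))
  tab <- regions$table
  if (!all(c("area_um2", "circularity") %in% names(tab)))
    stop("regions lack area/circularity measurements")
  small <- tab$area_um2 < filter$min_area_um2
  round_ <- tab$circularity >= filter$circ_window[1] &
            tab$circularity <= filter$circ_window[2]
  drop <- if (filter$mode == "conjunction") small & round_ else small
  keep <- tab$label[!drop]
  out <- regions
  out$labels <- relabel(regions$labels, keep)
  out$table <- tab[!drop, , drop = FALSE]
  out$table$label <- seq_along(keep)
  rownames(out$table) <- NULL
  out
}

#' Instance segmentation of nuclei
#'
#' Classical pipeline: Gaussian smoothing, global Otsu threshold (or a
#' supplied \code{\link{estimate_background}} model), hole filling, then a
#' distance-transform watershed to split touching nuclei. A learned-model
#' backend can be plugged in via \code{backend}: any function taking the
#' intensity matrix and returning an integer label matrix.
#'
#' @param image a \code{\link{calibrated_image}} or a numeric matrix.
#' @param channel channel to segment when \code{image} is multi-channel
#'   (default \code{"DAPI"}).
#' @param model optional background model; default is a global Otsu cut.
#' @param sigma Gaussian smoothing SD in pixels (default 2).
#' @param min_area_um2 discard instances smaller than this (default 20,
#'   well below any real nucleus at the calibrations used here).
#' @param tolerance watershed merge tolerance (default 1).
#' @param backend optional replacement segmentation function.
#' @param pixel_size pixel size in micrometres; required when \code{image}
#'   is a bare matrix.
#' @return a \code{\link{label_regions}} object measured on the segmented
#'   channel.
#' @export
segment_nuclei <- function(image, channel = "DAPI", model = NULL, sigma = 2,
                           min_area_um2 = 20, tolerance = 1, backend = NULL,
                           pixel_size = NULL) {
  if (inherits(image, "calibrated_image")) {
    ps <- image$pixel_size
    x <- get_channel(image, channel)
  } else {
    stopifnot(is.matrix(image), !is.null(pixel_size))
    ps <- pixel_size
    x <- image
  }
  if (length(dim(x)) != 2L) stop("segment_nuclei expects a single 2-D plane")
  if (!is.null(backend)) {
    lab <- backend(x)
    return(label_regions(lab, x, ps))
  }
  xs <- EBImage::gblur(x / 65535, sigma = sigma)
  if (is.null(model)) {
    thr <- otsu_threshold(xs)
    # bimodality guard: Otsu always returns a split, even on pure noise.
    # The separability eta = between-class / total variance is at most
    # ~2/pi for a unimodal Gaussian but close to 1 for stained nuclei on
    # background; below 0.8 there is nothing to segment.
    v <- as.numeric(xs)
    cls <- v > thr
    if (!any(cls) || all(cls)) return(label_regions(matrix(0L, nrow(x), ncol(x)), x, ps))
    eta <- (mean(cls) * (mean(v[cls]) - mean(v))^2 +
            mean(!cls) * (mean(v[!cls]) - mean(v))^2) / stats::var(v)
    if (eta < 0.8)
      return(label_regions(matrix(0L, nrow(x), ncol(x)), x, ps))
  } else thr <- model$threshold / 65535
  mask <- xs > thr
  if (!any(mask))
    return(label_regions(matrix(0L, nrow(x), ncol(x)), x, ps))
  mask <- EBImage::fillHull(mask)
  dm <- EBImage::distmap(mask)
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = tolerance))
  # drop specks below the minimum instance area
  sz <- tabulate(lab[lab > 0])
  keep <- which(sz * ps^2 >= min_area_um2)
  lab <- relabel(lab, keep)
  label_regions(lab, x, ps)
}

#' Global Otsu threshold
#'
#' Histogram-based between-class-variance maximization over the full array
#' (any dimensionality), with 512 bins spanning the data range. Returns a
#' threshold on the intensity scale of \code{x}; foreground is \code{x >}
#' threshold.
#'
#' @param x numeric array.
#' @param nbins histogram bins (default 512).
#' @return numeric threshold.
#' @export
otsu_threshold <- function(x, nbins = 512) {
  v <- as.numeric(x)
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  h <- as.numeric(tabulate(pmin(pmax(floor((v - r[1]) / (r[2] - r[1]) * nbins) + 1, 1),
                                nbins), nbins))
  w <- cumsum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) * (r[2] - r[1]) / nbins
  m <- cumsum(h * mids)
  n <- w[nbins]; mt <- m[nbins]
  w0 <- w[-nbins]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins - 1)
  bcv[valid] <- (mt * w0[valid] - n * m[-nbins][valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(bcv)
  r[1] + k * (r[2] - r[1]) / nbins
}

#' Segment muscle (MYH1 / alpha-actinin) area
#'
#' Median filter (radius 2 px), background-threshold positivity, connected
#' components, debris removal, then total area as the sum of surviving
#' region areas.
#'
#' @param image a \code{\link{calibrated_image}} or numeric matrix.
#' @param channel marker channel name (default \code{"MYH1"}).
#' @param model optional \code{\link{estimate_background}} model; estimated
#'   on the median-filtered image when missing.
#' @param filter a \code{\link{debris_filter}}.
#' @param median_radius median filter radius in pixels (default 2).
#' @param pixel_size required when \code{image} is a bare matrix.
#' @return list with \code{regions} (a \code{labeled_regions}),
#'   \code{total_area_um2}, \code{mask} (logical matrix), and \code{model}.
#' @export
segment_muscle <- function(image, channel = "MYH1", model = NULL,
                           filter = debris_filter(), median_radius = 2,
                           pixel_size = NULL) {
  if (inherits(image, "calibrated_image")) {
    ps <- image$pixel_size
    x <- get_channel(image, channel)
  } else {
    stopifnot(is.matrix(image), !is.null(pixel_size))
    ps <- pixel_size
    x <- image
  }
  xf <- EBImage::medianFilter(x / 65535, size = median_radius) * 65535
  # background statistics come from the unfiltered channel: the threshold is
  # defined against the acquisition noise, while the median filter only
  # suppresses speckle in the mask
  if (is.null(model)) model <- estimate_background(x)
  mask <- threshold_positive_mask(xf, model)
  lab <- EBImage::bwlabel(mask)
  regions <- label_regions(EBImage::imageData(lab), x, ps)
  regions <- filter_debris(regions, filter)
  list(regions = regions,
       total_area_um2 = sum(regions$table$area_um2),
       mask = regions$labels > 0,
       model = model)
}
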