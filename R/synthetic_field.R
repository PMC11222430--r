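#' Scene specification for the synthetic microscopy generator
#'
#' Parameterizes every synthetic image class the pipeline consumes. Defaults
#' mirror the acquisition geometry of the real experiments (0.28 um pixels
#' for single-plane myotube fields) and a culture density/marker mix typical
#' of day-4 differentiated hiPSC myotube wells.
#'
#' @param field_px field side length in pixels (default 384).
#' @param pixel_size_um lateral pixel size (default 0.28).
#' @param z_step_um axial step for stack presets (default 0.5).
#' @param frame_interval_s frame interval for movie presets (default 2).
#' @param n_nuclei number of nuclei to place (default 60).
#' @param n_myotubes number of myotube bands (default 3).
#' @param marker_positive_fraction fraction of nuclei positive for the
#'   nuclear marker (default 0.6).
#' @param marker_intensity_levels named vector \code{c(positive=, negative=)}
#'   mean nuclear marker intensities in AU (defaults 600 / 105: negative
#'   nuclei carry only faint near-background autofluorescence).
#' @param background_mean,background_sd background level and noise SD in AU
#'   (defaults 100, 5).
#' @param dapi_intensity,myotube_intensity,cluster_intensity mean intensities
#'   of nuclei in DAPI, myotube cytoplasm in MYH1, and receptor clusters in
#'   the aBGT channel (defaults 500, 400, 800).
#' @param striation_period_um optional sarcomeric striation period; when set,
#'   an alpha-actinin channel with sinusoidal intensity modulation along the
#'   myotube axis is added (default \code{NULL}; 2 um is near-sarcomeric).
#' @param cluster_specs list of \code{\link{cluster_spec}} objects placed on
#'   myotubes in an aBGT channel (default empty).
#' @param puncta_density_true true endocytic puncta density per 1000 um^3
#'   for the pulse-chase preset (default 5).
#' @param poisson_noise use Poisson shot noise instead of purely additive
#'   Gaussian noise (default FALSE).
#' @param rng_seed integer seed; identical spec + seed gives bit-identical
#'   output (default 1).
#' @return an object of class \code{scene_spec}.
#' @export
scene_spec <- function(field_px = 384, pixel_size_um = 0.28, z_step_um = 0.5,
                       frame_interval_s = 2, n_nuclei = 60, n_myotubes = 3,
                       marker_positive_fraction = 0.6,
                       marker_intensity_levels = c(positive = 600, negative = 105),
                       background_mean = 100, background_sd = 5,
                       dapi_intensity = 500, myotube_intensity = 400,
                       cluster_intensity = 800,
                       striation_period_um = NULL, cluster_specs = list(),
                       puncta_density_true = 5, poisson_noise = FALSE,
                       rng_seed = 1) {
  stopifnot(field_px >= 32, pixel_size_um > 0, z_step_um > 0,
            frame_interval_s > 0, n_nuclei >= 0, n_myotubes >= 0,
            marker_positive_fraction >= 0, marker_positive_fraction <= 1,
            all(marker_intensity_levels > 0), background_mean >= 0,
            background_sd >= 0, puncta_density_true >= 0)
  if (!is.null(striation_period_um)) stopifnot(striation_period_um > 0)
  structure(as.list(environment()), class = "scene_spec")
}

# additive Gaussian (or Poisson) camera noise, integer AU output
.add_noise <- function(signal, spec) {
  x <- if (spec$poisson_noise) {
    rpois(length(signal), pmax(signal, 0)) +
      rnorm(length(signal), 0, spec$background_sd)
  } else {
    signal + rnorm(length(signal), 0, spec$background_sd)
  }
  out <- round(pmin(pmax(x, 0), 65535))
  dim(out) <- dim(signal)
  out
}

# paint an ellipse; returns logical matrix of the spec'd canvas
.ellipse_mask <- function(ny, nx, cy, cx, a, b, theta) {
  y <- matrix(seq_len(ny), ny, nx) - cy
  x <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - cx
  u <- cos(theta) * x + sin(theta) * y
  v <- -sin(theta) * x + cos(theta) * y
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate a multi-channel synthetic myotube field with ground truth
#'
#' Renders a calibrated 2-D field with channels DAPI (all nuclei), MyoG
#' (nuclear marker, positive nuclei at the positive mean and the rest at the
#' negative mean), MYH1 (myotube cytoplasm), optionally ACTN (striated) and
#' aBGT (receptor clusters from \code{cluster_specs}). Nuclei are
#' non-overlapping ellipses with bounded eccentricity placed by rejection
#' sampling; myotubes are oblique capsule-shaped bands spanning the field.
#'
#' @param spec a \code{\link{scene_spec}}.
#' @return list with \code{image} (a \code{\link{calibrated_image}}) and
#'   \code{truth}: \code{nucleus_labels} (integer matrix),
#'   \code{nucleus_positive} (logical per nucleus), \code{nucleus_centroids}
#'   (n x 2 matrix, y/x px), \code{in_muscle} (logical per nucleus),
#'   \code{myotube_mask}, \code{muscle_area_um2}, \code{cluster_labels},
#'   \code{n_clusters}, plus the spec itself.
#' @export
generate_myotube_field <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$rng_seed, .generate_field_impl(spec))
}

.generate_field_impl <- function(spec) {
  n <- spec$field_px
  ps <- spec$pixel_size_um
  # myotube bands: oblique capsules through the field
  tube_mask <- matrix(FALSE, n, n)
  tube_axes <- list()
  ygrid <- matrix(seq_len(n), n, n)
  xgrid <- matrix(seq_len(n), n, n, byrow = TRUE)
  if (spec$n_myotubes > 0) {
    slots <- seq(0.15, 0.85, length.out = spec$n_myotubes)
    for (i in seq_len(spec$n_myotubes)) {
      cy <- slots[i] * n + runif(1, -0.03, 0.03) * n
      ang <- runif(1, -pi / 9, pi / 9)
      hw <- runif(1, 5, 7) / ps          # half-width: 10-14 um wide tubes
      d <- abs(-sin(ang) * (xgrid - n / 2) + cos(ang) * (ygrid - cy))
      tube_mask <- tube_mask | (d <= hw)
      tube_axes[[i]] <- list(cy = cy, angle = ang, half_width = hw)
    }
  }
  # nuclei: rejection-sampled non-overlapping ellipses
  nuc_labels <- matrix(0L, n, n)
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  params <- list()
  tries <- 0L
  max_tries <- 400L * max(spec$n_nuclei, 1L)
  margin <- min(5 / ps, 0.05 * n)
  while (nrow(centers) < spec$n_nuclei) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("placement failure: could not place ", spec$n_nuclei,
           " non-overlapping nuclei in a ", n, "-px field")
    a <- runif(1, 3.2, 4.2) / ps
    b <- runif(1, 2.4, 3.2) / ps
    if (margin + a >= n - margin - a)
      stop("placement failure: field too small for ", spec$n_nuclei, " nuclei")
    cy <- runif(1, margin + a, n - margin - a)
    cx <- runif(1, margin + a, n - margin - a)
    if (nrow(centers) > 0 &&
        any(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) <
            radii + a + 2)) next
    centers <- rbind(centers, c(cy, cx))
    radii <- c(radii, a)
    params[[length(params) + 1L]] <- c(a = a, b = b, theta = runif(1, 0, pi))
  }
  for (i in seq_len(nrow(centers))) {
    p <- params[[i]]
    m <- .ellipse_mask(n, n, centers[i, 1], centers[i, 2], p["a"], p["b"], p["theta"])
    nuc_labels[m] <- i
  }
  n_placed <- nrow(centers)
  # Bernoulli draw per nucleus: replicate fields then vary binomially around
  # the requested fraction, as wells of a real culture do
  positive <- if (n_placed > 0)
    runif(n_placed) < spec$marker_positive_fraction else logical(0)
  in_muscle <- rep(FALSE, n_placed)
  if (n_placed > 0)
    in_muscle <- tube_mask[cbind(pmin(pmax(round(centers[, 1]), 1), n),
                                 pmin(pmax(round(centers[, 2]), 1), n))]
  # channels
  lv <- spec$marker_intensity_levels
  bg <- spec$background_mean
  dapi <- matrix(bg, n, n); dapi[nuc_labels > 0] <- spec$dapi_intensity
  myog <- matrix(bg, n, n)
  if (n_placed > 0) {
    myog[nuc_labels > 0 & matrix(positive[pmax(nuc_labels, 1)], n, n)] <- lv["positive"]
    myog[nuc_labels > 0 & !matrix(positive[pmax(nuc_labels, 1)], n, n)] <- lv["negative"]
  }
  myh1 <- matrix(bg, n, n); myh1[tube_mask] <- spec$myotube_intensity
  chans <- list(DAPI = dapi, MyoG = myog, MYH1 = myh1)
  if (!is.null(spec$striation_period_um) && spec$n_myotubes > 0) {
    actn <- matrix(bg, n, n)
    for (tb in tube_axes) {
      d_ax <- cos(tb$angle) * (xgrid - n / 2) + sin(tb$angle) * (ygrid - tb$cy)
      mod <- 1 + 0.3 * sin(2 * pi * d_ax * ps / spec$striation_period_um)
      sel <- abs(-sin(tb$angle) * (xgrid - n / 2) + cos(tb$angle) * (ygrid - tb$cy)) <= tb$half_width
      actn[sel] <- spec$myotube_intensity * mod[sel]
    }
    chans$ACTN <- actn
  }
  cluster_labels <- matrix(0L, n, n)
  if (length(spec$cluster_specs) > 0) {
    abgt <- matrix(bg, n, n)
    tube_idx <- which(tube_mask & ygrid > 20 & ygrid < n - 20 &
                        xgrid > 20 & xgrid < n - 20)
    ci <- 0L
    for (cs in spec$cluster_specs) {
      ci <- ci + 1L
      cs$pixel_size_um <- ps
      cmask <- generate_cluster_mask(cs)
      # drop at a random on-myotube position (top-left anchor)
      ok <- FALSE
      for (try in 1:50) {
        at <- tube_idx[sample.int(length(tube_idx), 1)]
        ay <- ((at - 1) %% n) + 1; ax <- ((at - 1) %/% n) + 1
        y1 <- ay - nrow(cmask) %/% 2; x1 <- ax - ncol(cmask) %/% 2
        if (y1 < 1 || x1 < 1 || y1 + nrow(cmask) - 1 > n ||
            x1 + ncol(cmask) - 1 > n) next
        sub <- cluster_labels[y1:(y1 + nrow(cmask) - 1), x1:(x1 + ncol(cmask) - 1)]
        if (any(sub[cmask] > 0)) next
        sub[cmask] <- ci
        cluster_labels[y1:(y1 + nrow(cmask) - 1), x1:(x1 + ncol(cmask) - 1)] <- sub
        ok <- TRUE
        break
      }
      if (!ok) stop("placement failure: could not place cluster ", ci)
    }
    abgt[cluster_labels > 0] <- spec$cluster_intensity
    chans$aBGT <- abgt
  }
  arr <- array(0, c(n, n, length(chans)))
  for (i in seq_along(chans)) arr[, , i] <- .add_noise(chans[[i]], spec)
  img <- calibrated_image(arr, axes = c("Y", "X", "C"), pixel_size = ps,
                          channels = names(chans))
  truth <- list(nucleus_labels = nuc_labels, nucleus_positive = positive,
                nucleus_centroids = centers, in_muscle = in_muscle,
                n_nuclei = n_placed,
                pct_positive = if (n_placed > 0) 100 * mean(positive) else NA_real_,
                pct_in_muscle = if (n_placed > 0) 100 * mean(in_muscle) else NA_real_,
                myotube_mask = tube_mask,
                muscle_area_um2 = sum(tube_mask) * ps^2,
                cluster_labels = cluster_labels,
                n_clusters = length(spec$cluster_specs),
                spec = spec)
  list(image = img, truth = truth)
}
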