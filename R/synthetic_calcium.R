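#' Transient parameters for the calcium-movie generator
#'
#' The simulated Fluo4 response of a myotube to agonist addition: baseline
#' \code{f0} until the stimulus, a linear rise over \code{rise_s} seconds to
#' \code{f0 + amplitude}, then exponential decay with time constant
#' \code{decay_s}. A sham fluid addition at \code{t_sham} adds
#' \code{sham_amplitude} with the same kinetics (0 by default: the control
#' condition where medium addition alone must produce no transient).
#'
#' @param f0 baseline fluorescence (AU, default 100).
#' @param amplitude peak amplitude above baseline (AU, default 50).
#' @param rise_s rise time to peak (s, default 4).
#' @param decay_s exponential decay constant (s, default 20).
#' @param t_stim stimulus time (s, default 60 — agonist applied after 1 min
#'   of imaging).
#' @param t_sham sham-addition time (s, default 30) or \code{NULL}.
#' @param sham_amplitude amplitude of the sham event (AU, default 0).
#' @param duration_s movie length (s, default 120).
#' @param noise_sd additive Gaussian noise SD per pixel (AU, default 5).
#' @return an object of class \code{transient_params}.
#' @export
transient_params <- function(f0 = 100, amplitude = 50, rise_s = 4,
                             decay_s = 20, t_stim = 60, t_sham = 30,
                             sham_amplitude = 0, duration_s = 120,
                             noise_sd = 5) {
  stopifnot(f0 > 0, amplitude >= 0, rise_s > 0, decay_s > 0, t_stim > 0,
            duration_s > 0, noise_sd >= 0)
  if (t_stim >= duration_s)
    stop("stimulus time must fall within the movie duration")
  if (!is.null(t_sham) && t_sham >= t_stim)
    stop("sham addition must precede the stimulus")
  structure(as.list(environment()), class = "transient_params")
}

# noiseless pulse profile: 0 before t0, linear rise, exponential decay
.pulse <- function(t, t0, amp, rise_s, decay_s) {
  out <- numeric(length(t))
  up <- t > t0 & t <= t0 + rise_s
  out[up] <- amp * (t[up] - t0) / rise_s
  dn <- t > t0 + rise_s
  out[dn] <- amp * exp(-(t[dn] - t0 - rise_s) / decay_s)
  out
}

#' Generate a synthetic Fluo4 calcium movie with ground truth
#'
#' Myotubes are horizontal bands whose pixels follow the transient of
#' \code{params}; everything else is background. Noise is additive Gaussian
#' per pixel and frame. The true peak \eqn{\Delta F/F_0} under the
#' normalization \eqn{(F - F_0)/F} is \code{amplitude / (f0 + amplitude)}.
#'
#' @param spec a \code{\link{scene_spec}} (movie geometry: \code{field_px},
#'   \code{pixel_size_um}, \code{frame_interval_s}, \code{n_myotubes},
#'   \code{background_mean}, \code{rng_seed}).
#' @param params a \code{\link{transient_params}}.
#' @return list with \code{image} (a \code{\link{calibrated_image}} with a
#'   time axis, channel \code{"Fluo4"}), \code{roi_labels} (integer matrix
#'   of myotube ROIs) and \code{truth} (transient parameters, frame times,
#'   \code{true_peak_dff}, \code{t_peak}).
#' @export
generate_calcium_movie <- function(spec, params = transient_params()) {
  stopifnot(inherits(spec, "scene_spec"), inherits(params, "transient_params"))
  with_seed(spec$rng_seed, {
    n <- spec$field_px
    dt <- spec$frame_interval_s
    nt <- floor(params$duration_s / dt)
    t <- dt * seq_len(nt)
    roi <- matrix(0L, n, n)
    k <- max(spec$n_myotubes, 1L)
    band_h <- max(4L, floor(n / (2 * k + 1)))
    for (i in seq_len(k)) {
      y0 <- floor((2 * i - 1) / (2 * k + 1) * n)
      roi[y0:(y0 + band_h - 1), ] <- i
    }
    f_t <- params$f0 + .pulse(t, params$t_stim, params$amplitude,
                              params$rise_s, params$decay_s)
    if (!is.null(params$t_sham) && params$sham_amplitude > 0)
      f_t <- f_t + .pulse(t, params$t_sham, params$sham_amplitude,
                          params$rise_s, params$decay_s)
    arr <- array(0, c(n, n, 1, 1, nt))
    base <- matrix(spec$background_mean, n, n)
    for (j in seq_len(nt)) {
      frame <- base
      frame[roi > 0] <- f_t[j]
      frame <- frame + rnorm(n * n, 0, params$noise_sd)
      arr[, , 1, 1, j] <- round(pmin(pmax(frame, 0), 65535))
    }
    img <- calibrated_image(arr, axes = c("Y", "X", "C", "Z", "T"),
                            pixel_size = spec$pixel_size_um,
                            frame_interval = dt, channels = "Fluo4")
    truth <- list(params = params, times = t,
                  true_peak_dff = params$amplitude / (params$f0 + params$amplitude),
                  t_peak = params$t_stim + params$rise_s)
    list(image = img, roi_labels = roi, truth = truth)
  })
}
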