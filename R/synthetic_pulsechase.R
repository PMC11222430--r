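#' Generate a two-channel pulse-chase z-stack with ground truth
#'
#' Emulates sequential two-color surface-receptor labeling: the "old" label
#' channel carries the surface cluster plus discrete intracellular endocytic
#' puncta at the true density; the "new" label channel carries the surface
#' cluster plus a dim myotube outline (the shell that makes the myotube
#' segmentable). The myotube is a cylinder along X; puncta are Gaussian
#' blobs placed uniformly inside it (Poisson count at
#' \code{spec$puncta_density_true} per 1000 um^3), kept clear of the surface
#' cluster and of each other.
#'
#' @param spec a \code{\link{scene_spec}}; relevant fields: \code{field_px}
#'   (XY size), \code{pixel_size_um}, \code{z_step_um},
#'   \code{background_mean}, \code{background_sd},
#'   \code{puncta_density_true}, \code{rng_seed}.
#' @param n_z number of z-planes (default 24).
#' @param tube_radius_um cylinder radius (default 5).
#' @param puncta_snr punctum peak amplitude in units of the background SD
#'   (default 8).
#' @param shell_intensity outline intensity in AU (default 180).
#' @param cluster_intensity surface-cluster intensity (default 500).
#' @return list with \code{image} (channels \code{old_label},
#'   \code{new_label}) and \code{truth}: \code{myotube_mask} (3-D logical),
#'   \code{volume_um3}, \code{puncta_coords} (n x 3, y/x/z px),
#'   \code{n_puncta}, \code{density_true} (per 1000 um^3, from the placed
#'   count), \code{cluster_mask}, \code{cluster_centroid_px}.
#' @export
generate_pulse_chase_stack <- function(spec, n_z = 24, tube_radius_um = 5,
                                       puncta_snr = 8, shell_intensity = 180,
                                       cluster_intensity = 500) {
  stopifnot(inherits(spec, "scene_spec"), spec$puncta_density_true >= 0)
  with_seed(spec$rng_seed, {
    n <- spec$field_px
    ps <- spec$pixel_size_um
    zs <- spec$z_step_um
    voxvol <- ps^2 * zs
    yc <- n / 2
    zc <- n_z / 2
    r_px_y <- tube_radius_um / ps
    r_px_z <- tube_radius_um / zs
    ygr <- array(rep(seq_len(n), times = n * n_z), c(n, n, n_z))
    zgr <- array(rep(seq_len(n_z), each = n * n), c(n, n, n_z))
    rad2 <- ((ygr - yc) / r_px_y)^2 + ((zgr - zc) / r_px_z)^2
    tube <- rad2 <= 1
    # membrane outline: the 2-voxel-thick inner boundary of the tube (a
    # closed ring in every cross-section regardless of z anisotropy)
    shell <- tube & !erode_ball1_3d(erode_ball1_3d(tube))
    vol <- sum(tube) * voxvol
    # surface cluster: patch on the top surface at the stack center
    xc <- n / 2
    xgr <- array(rep(seq_len(n), each = n), c(n, n, n_z))
    top_y <- yc
    top_z <- zc + r_px_z - 0.5
    clr <- 1.5 / ps
    cluster <- shell & ((xgr - xc)^2 + (ygr - top_y)^2) <= clr^2 & zgr > zc
    cl_idx <- which(cluster, arr.ind = TRUE)
    cl_cen <- if (nrow(cl_idx)) colMeans(cl_idx) else c(yc, xc, n_z)
    # puncta: Poisson count at the true density, uniform inside the tube,
    # clear of the cluster footprint and of each other
    lambda <- spec$puncta_density_true * vol / 1000
    n_target <- rpois(1, lambda)
    inside <- which(tube & !cluster)
    min_sep_px <- 1.5 / ps
    coords <- matrix(numeric(0), 0, 3)
    tries <- 0L
    while (nrow(coords) < n_target && tries < 200L * max(n_target, 1L)) {
      tries <- tries + 1L
      at <- inside[sample.int(length(inside), 1)]
      a0 <- at - 1L
      y <- (a0 %% n) + 1L
      x <- ((a0 %/% n) %% n) + 1L
      z <- (a0 %/% (n * n)) + 1L
      # keep clear of the surface cluster and the stack border
      if (z < 2 || z > n_z - 1 || x < 4 || x > n - 3 || y < 4 || y > n - 3) next
      if (sqrt((y - cl_cen[1])^2 + (x - cl_cen[2])^2) < 2 * clr &&
          abs(z - cl_cen[3]) < 4) next
      if (nrow(coords) > 0 &&
          any(sqrt((coords[, 1] - y)^2 + (coords[, 2] - x)^2 +
                   ((coords[, 3] - z) * zs / ps)^2) < min_sep_px)) next
      coords <- rbind(coords, c(y, x, z))
    }
    n_puncta <- nrow(coords)
    amp <- puncta_snr * max(spec$background_sd, 1)
    sig_xy <- 0.25 / ps
    sig_z <- 0.4 / zs
    old <- array(spec$background_mean, c(n, n, n_z))
    if (n_puncta > 0) {
      for (i in seq_len(n_puncta)) {
        y <- coords[i, 1]; x <- coords[i, 2]; z <- coords[i, 3]
        wy <- ceiling(3 * sig_xy); wz <- ceiling(3 * sig_z)
        ys <- max(1, y - wy):min(n, y + wy)
        xs <- max(1, x - wy):min(n, x + wy)
        zl <- max(1, z - wz):min(n_z, z + wz)
        g <- outer(exp(-((ys - y)^2) / (2 * sig_xy^2)),
                   exp(-((xs - x)^2) / (2 * sig_xy^2)))
        for (zz in zl)
          old[ys, xs, zz] <- old[ys, xs, zz] +
            amp * g * exp(-((zz - z)^2) / (2 * sig_z^2))
      }
    }
    old[cluster] <- old[cluster] + cluster_intensity
    new <- array(spec$background_mean, c(n, n, n_z))
    new[shell] <- shell_intensity
    new[cluster] <- cluster_intensity
    arr <- array(0, c(n, n, 2, n_z, 1))
    for (z in seq_len(n_z)) {
      arr[, , 1, z, 1] <- .add_noise(old[, , z], spec)
      arr[, , 2, z, 1] <- .add_noise(new[, , z], spec)
    }
    img <- calibrated_image(arr, axes = c("Y", "X", "C", "Z", "T"),
                            pixel_size = ps, z_step = zs,
                            channels = c("old_label", "new_label"))
    truth <- list(myotube_mask = tube, volume_um3 = vol,
                  puncta_coords = coords, n_puncta = n_puncta,
                  density_true = 1000 * n_puncta / vol,
                  cluster_mask = cluster, cluster_centroid_px = cl_cen,
                  spec = spec)
    list(image = img, truth = truth)
  })
}
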