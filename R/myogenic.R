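#' Percentage of marker-positive nuclei
#'
#' A nucleus is positive when its mean intensity in the marker channel
#' strictly exceeds the background threshold \eqn{\mu_{bg} + k\,\sigma_{bg}}.
#'
#' @param nuclei a \code{\link{label_regions}} object (nuclei instances).
#' @param marker numeric matrix, marker channel co-registered with the
#'   nuclei label map.
#' @param model a \code{\link{estimate_background}} model for the marker
#'   channel.
#' @return percentage in \[0, 100\]; \code{NA} with a warning when there are
#'   no nuclei.
#' @export
pct_positive_nuclei <- function(nuclei, marker, model) {
  stopifnot(inherits(nuclei, "labeled_regions"),
            identical(dim(marker), dim(nuclei$labels)))
  if (n_regions(nuclei) == 0)
    return(.nmj_sentinel("no nuclei: positive percentage undefined"))
  means <- .region_means(nuclei, marker)
  100 * mean(means > .thr(model))
}

.thr <- function(model)
  if (inherits(model, "background_model")) model$threshold else model

.region_means <- function(regions, image) {
  lab <- regions$labels
  as.numeric(tapply(image[lab > 0], lab[lab > 0], mean))
}

#' Differentiation index
#'
#' Percentage of all nuclei whose centroid lies inside the muscle
#' (MYH1-positive) mask — the fraction of nuclei recruited into myotubes.
#'
#' @param nuclei a \code{\link{label_regions}} object.
#' @param muscle_mask logical matrix.
#' @param min_overlap alternative membership rule: when > 0, a nucleus
#'   counts as inside if at least this fraction of its pixels overlaps the
#'   mask, instead of the centroid rule (default 0 = centroid rule).
#' @return percentage in \[0, 100\]; \code{NA} with a warning for zero nuclei.
#' @export
differentiation_index <- function(nuclei, muscle_mask, min_overlap = 0) {
  stopifnot(inherits(nuclei, "labeled_regions"),
            identical(dim(muscle_mask), dim(nuclei$labels)))
  if (n_regions(nuclei) == 0)
    return(.nmj_sentinel("no nuclei: differentiation index undefined"))
  if (min_overlap > 0) {
    lab <- nuclei$labels
    ov <- tapply(muscle_mask[lab > 0], lab[lab > 0], mean)
    return(100 * mean(as.numeric(ov) >= min_overlap))
  }
  ps <- nuclei$pixel_size
  cy <- pmin(pmax(round(nuclei$table$centroid_y_um / ps) + 1, 1), nrow(muscle_mask))
  cx <- pmin(pmax(round(nuclei$table$centroid_x_um / ps) + 1, 1), ncol(muscle_mask))
  100 * mean(muscle_mask[cbind(cy, cx)])
}

#' Mean fluorescence intensity of marker-positive regions
#'
#' Mean of the per-region mean intensities over regions whose mean exceeds
#' the background threshold (cell-level averaging).
#'
#' @param regions a \code{\link{label_regions}} object.
#' @param marker numeric matrix, marker channel.
#' @param model background model for that channel.
#' @return mean intensity in AU; \code{NA} with a warning when no region is
#'   positive.
#' @export
mfi_positive <- function(regions, marker, model) {
  stopifnot(inherits(regions, "labeled_regions"))
  if (n_regions(regions) == 0)
    return(.nmj_sentinel("no regions: MFI undefined"))
  means <- .region_means(regions, marker)
  pos <- means > .thr(model)
  if (!any(pos)) return(.nmj_sentinel("no positive regions: MFI undefined"))
  mean(means[pos])
}

#' Myonuclear domain area
#'
#' Total muscle cell area divided by the number of myonuclei; the area of
#' cytoplasm each nucleus supports.
#'
#' @param total_muscle_area_um2 total muscle area in square micrometres.
#' @param n_myonuclei number of nuclei inside muscle (> 0).
#' @return area per nucleus in square micrometres.
#' @export
#' @examples
#' myonuclear_domain(10000, 20)  # 500
myonuclear_domain <- function(total_muscle_area_um2, n_myonuclei) {
  stopifnot(total_muscle_area_um2 >= 0)
  if (n_myonuclei <= 0) stop("myonuclear domain undefined for zero myonuclei")
  total_muscle_area_um2 / n_myonuclei
}

#' Receptor cluster density per muscle area
#'
#' @param n_clusters cluster count.
#' @param muscle_area_um2 muscle area in square micrometres (> 0).
#' @return clusters per 1000 square micrometres.
#' @export
#' @examples
#' cluster_density(3, 1500)  # 2
cluster_density <- function(n_clusters, muscle_area_um2) {
  stopifnot(n_clusters >= 0)
  if (muscle_area_um2 <= 0) stop("cluster density undefined for zero area")
  1000 * n_clusters / muscle_area_um2
}

#' Integrated density over a mask
#'
#' Sum of pixel intensities over the mask times the physical pixel area.
#'
#' @param mask logical matrix.
#' @param image numeric matrix, co-registered.
#' @param pixel_size_um pixel size in micrometres.
#' @return integrated density in AU um^2.
#' @export
#' @examples
#' integrated_density(matrix(TRUE, 10, 10), matrix(10, 10, 10), 0.28)
integrated_density <- function(mask, image, pixel_size_um) {
  stopifnot(identical(dim(mask), dim(image)), pixel_size_um > 0)
  sum(image[mask]) * pixel_size_um^2
}

#' Full per-image myogenic readout
#'
#' Convenience wrapper running the standard readout set on one
#' multi-channel field: nuclei segmentation, marker positivity, muscle
#' segmentation, differentiation index, myonuclear domain, and (when an
#' aBGT channel is present) cluster density and integrated density.
#'
#' @param image a \code{\link{calibrated_image}} with channels DAPI, MyoG,
#'   MYH1 and optionally aBGT.
#' @param filter a \code{\link{debris_filter}} for muscle segmentation.
#' @param k background threshold multiplier (default 2).
#' @return one-row data frame of class readouts.
#' @export
myogenic_readout <- function(image, filter = debris_filter(), k = 2) {
  stopifnot(inherits(image, "calibrated_image"))
  nuclei <- segment_nuclei(image, "DAPI")
  myog <- get_channel(image, "MyoG")
  m_myog <- estimate_background(myog, k = k)
  muscle <- segment_muscle(image, "MYH1", filter = filter)
  n_nuc <- n_regions(nuclei)
  dix <- differentiation_index(nuclei, muscle$mask)
  n_myo <- if (n_nuc > 0) round(dix / 100 * n_nuc) else 0L
  out <- data.frame(
    n_nuclei = n_nuc,
    pct_myog_positive = pct_positive_nuclei(nuclei, myog, m_myog),
    differentiation_index = dix,
    mfi_myog_positive = mfi_positive(nuclei, myog, m_myog),
    total_muscle_area_um2 = muscle$total_area_um2,
    n_myonuclei = n_myo,
    mnd_area_um2 = if (n_myo > 0)
      myonuclear_domain(muscle$total_area_um2, n_myo) else NA_real_)
  if ("aBGT" %in% image$channels) {
    ab <- get_channel(image, "aBGT")
    m_ab <- estimate_background(ab, k = k)
    cl_mask <- threshold_positive_mask(ab, m_ab) & muscle$mask
    cl_lab <- EBImage::bwlabel(cl_mask)
    cl <- label_regions(EBImage::imageData(cl_lab), ab, image$pixel_size)
    # specks below 1 um^2 are noise, not clusters
    keep <- cl$table$label[cl$table$area_um2 >= 1]
    n_cl <- length(keep)
    out$n_clusters <- n_cl
    out$cluster_density_per_1000um2 <- if (muscle$total_area_um2 > 0)
      cluster_density(n_cl, muscle$total_area_um2) else NA_real_
    out$abgt_integrated_density <- integrated_density(cl_mask, ab, image$pixel_size)
  }
  out
}
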