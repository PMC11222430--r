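#' 3-D morphology primitives
#'
#' Binary erosion/dilation with the radius-1 ball (6-connected cross) in
#' voxel units, connected-components labeling, local maxima, and separable
#' Gaussian smoothing for 3-D stacks. Anisotropy between z and xy is
#' deliberately ignored by the ball elements (radius-in-voxels semantics, as
#' in ImageJ/MorphoLibJ).
#'
#' @param x 3-D logical (morphology) or numeric (smoothing) array.
#' @return array of the same dimensions.
#' @name morphology3d
NULL

# shift a 3-D array by one voxel along dim `d` in direction `s`, replicating
# the edge plane for numeric inputs and padding FALSE for logical
.shift3 <- function(x, d, s, pad) {
  dm <- dim(x)
  idx <- lapply(dm, seq_len)
  src <- idx
  if (s > 0) src[[d]] <- c(1L, seq_len(dm[d] - 1L)) else
             src[[d]] <- c(seq_len(dm[d] - 1L) + 1L, dm[d])
  out <- do.call(`[`, c(list(x), src, list(drop = FALSE)))
  edge <- idx
  edge[[d]] <- if (s > 0) 1L else dm[d]
  if (!missing(pad)) {
    ass <- function(a, i, v) {do.call(`[<-`, c(list(a), i, list(v)))}
    out <- ass(out, edge, pad)
  }
  out
}

#' @rdname morphology3d
#' @export
dilate_ball1_3d <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  out <- x
  for (d in 1:3) for (s in c(-1, 1))
    out <- out | .shift3(x, d, s, pad = FALSE)
  out
}

#' @rdname morphology3d
#' @export
erode_ball1_3d <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  out <- x
  for (d in 1:3) for (s in c(-1, 1))
    out <- out & .shift3(x, d, s, pad = FALSE)
  out
}

#' @rdname morphology3d
#' @export
open_ball1_3d <- function(x) dilate_ball1_3d(erode_ball1_3d(x))

#' 3-D connected-components labeling (6-connectivity)
#'
#' @param mask 3-D logical array.
#' @return integer array; components numbered from 1 in first-voxel
#'   (column-major) order, 0 = background.
#' @export
label_components_3d <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  dm <- dim(mask)
  out <- array(0L, dm)
  fg <- which(mask)
  if (length(fg) == 0) return(out)
  pos <- integer(prod(dm))
  pos[fg] <- seq_along(fg)
  a0 <- fg - 1L
  y <- (a0 %% dm[1]) + 1L
  x <- ((a0 %/% dm[1]) %% dm[2]) + 1L
  z <- (a0 %/% (dm[1] * dm[2])) + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))) {
    ok <- (y + off[1] <= dm[1]) & (x + off[2] <= dm[2]) & (z + off[3] <= dm[3])
    nb <- fg[ok] + off[1] + off[2] * dm[1] + off[3] * dm[1] * dm[2]
    hit <- pos[nb] > 0L
    edges <- c(edges, rbind(pos[fg[ok]][hit], pos[nb][hit]))
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  # renumber components by first occurrence so labeling is deterministic
  first <- !duplicated(comp)
  ren <- integer(max(comp))
  ren[comp[first]] <- seq_len(sum(first))
  out[fg] <- ren[comp]
  out
}

#' @rdname morphology3d
#' @export
local_max_3d <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  out <- array(TRUE, dim(x))
  for (dy in -1:1) for (dx in -1:1) for (dz in -1:1) {
    if (dy == 0 && dx == 0 && dz == 0) next
    nb <- x
    if (dy != 0) nb <- .shift3(nb, 1, dy, pad = -Inf)
    if (dx != 0) nb <- .shift3(nb, 2, dx, pad = -Inf)
    if (dz != 0) nb <- .shift3(nb, 3, dz, pad = -Inf)
    out <- out & (x >= nb)
  }
  out
}

#' Separable Gaussian smoothing of a 3-D stack
#'
#' @param x numeric 3-D array.
#' @param sigma_px lateral sigma in pixels.
#' @param sigma_z axial sigma in planes.
#' @return smoothed numeric array.
#' @export
gaussian_smooth_3d <- function(x, sigma_px = 1, sigma_z = 0.75) {
  stopifnot(length(dim(x)) == 3L)
  ker <- function(s) {
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(-r:r)^2 / (2 * s^2))
    k / sum(k)
  }
  conv_dim <- function(x, d, k) {
    r <- (length(k) - 1L) %/% 2L
    out <- array(0, dim(x))
    for (i in seq_along(k)) {
      sh <- x
      nsh <- i - r - 1L
      if (nsh != 0) for (j in seq_len(abs(nsh)))
        sh <- .shift3(sh, d, sign(nsh))
      out <- out + k[i] * sh
    }
    out
  }
  x <- conv_dim(x, 1, ker(sigma_px))
  x <- conv_dim(x, 2, ker(sigma_px))
  conv_dim(x, 3, ker(sigma_z))
}
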