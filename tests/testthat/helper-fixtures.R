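# fixtures and independent oracles shared across tests

# digital disk mask: pixel centers within r of the canvas center
make_disk <- function(r, pad = 4) {
  n <- 2 * r + 2 * pad + 1
  c0 <- r + pad + 1
  iy <- matrix(seq_len(n), n, n)
  ix <- t(iy)
  (iy - c0)^2 + (ix - c0)^2 <= r^2
}

# plus-sign polyomino: square core with four 1-px-wide arms
make_plus <- function(arm = 3, pad = 3) {
  n <- 2 * arm + 1 + 2 * pad
  c0 <- arm + pad + 1
  m <- matrix(FALSE, n, n)
  m[c0, (c0 - arm):(c0 + arm)] <- TRUE
  m[(c0 - arm):(c0 + arm), c0] <- TRUE
  m
}

# independent convex hull by gift wrapping (Jarvis march) on (y, x) points
oracle_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n <= 2) return(pts)
  start <- which.min(pts[, 2] + pts[, 1] * 1e-9)
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    best <- cand[1]
    for (q in cand[-1]) {
      cr <- (pts[best, 1] - pts[p, 1]) * (pts[q, 2] - pts[p, 2]) -
            (pts[best, 2] - pts[p, 2]) * (pts[q, 1] - pts[p, 1])
      if (cr < 0 ||
          (cr == 0 && sum((pts[q, ] - pts[p, ])^2) > sum((pts[best, ] - pts[p, ])^2)))
        best <- q
    }
    if (best == start) break
    hull <- c(hull, best)
    if (length(hull) > n) stop("hull oracle failed to close")
  }
  pts[hull, , drop = FALSE]
}

# lattice points inside a polygon by even-odd ray casting (boundary counts in)
oracle_points_in_poly <- function(poly, pts) {
  n <- nrow(poly)
  inside <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    y <- pts[i, 1]; x <- pts[i, 2]
    cnt <- 0
    on_edge <- FALSE
    for (j in seq_len(n)) {
      k <- if (j == n) 1 else j + 1
      y1 <- poly[j, 1]; x1 <- poly[j, 2]
      y2 <- poly[k, 1]; x2 <- poly[k, 2]
      # point on segment?
      cr <- (y2 - y1) * (x - x1) - (x2 - x1) * (y - y1)
      if (abs(cr) < 1e-9 && x >= min(x1, x2) - 1e-9 && x <= max(x1, x2) + 1e-9 &&
          y >= min(y1, y2) - 1e-9 && y <= max(y1, y2) + 1e-9) on_edge <- TRUE
      if ((y1 > y) != (y2 > y)) {
        xin <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        if (x < xin) cnt <- cnt + 1
      }
    }
    inside[i] <- on_edge || (cnt %% 2 == 1)
  }
  inside
}

# oracle solidity under the package convention, via the independent hull
oracle_solidity <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  storage.mode(idx) <- "double"
  if (nrow(idx) <= 3) return(1)
  hull <- oracle_hull(idx)
  bb <- expand.grid(y = min(idx[, 1]):max(idx[, 1]),
                    x = min(idx[, 2]):max(idx[, 2]))
  nrow(idx) / sum(oracle_points_in_poly(hull, as.matrix(bb)))
}

# small calibrated field used by several IO tests
tiny_field <- function(seed = 2, n = 128, nuclei = 6) {
  generate_myotube_field(scene_spec(field_px = n, n_nuclei = nuclei,
                                    rng_seed = seed))
}
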