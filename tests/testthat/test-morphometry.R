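test_that("max-z projection equals the per-pixel brute-force maximum", {
  single <- array(runif(64), c(8, 8, 1))
  expect_equal(project_max_z(single), single[, , 1])

  two <- array(0, c(8, 8, 2))
  two[2, 2, 1] <- 5
  two[6, 6, 2] <- 7
  pr <- project_max_z(two)
  expect_equal(pr[2, 2], 5)
  expect_equal(pr[6, 6], 7)

  set.seed(8)
  st <- array(runif(32^3), c(32, 32, 32))
  pr <- project_max_z(st)
  oracle <- matrix(0, 32, 32)
  for (i in 1:32) for (j in 1:32) oracle[i, j] <- max(st[i, j, ])
  expect_equal(pr, oracle)

  expect_error(project_max_z(array(1, c(4, 4, 4, 4))), "Y, X, Z")
})

test_that("cluster segmentation isolates one cluster from its crop", {
  m <- generate_cluster_mask(cluster_spec(10, 0.9, 1, rng_seed = 3))
  crop <- matrix(100, nrow(m) + 8, ncol(m) + 8)
  crop[5:(4 + nrow(m)), 5:(4 + ncol(m))][m] <- 600
  set.seed(2)
  crop <- crop + matrix(rnorm(length(crop), 0, 50), nrow(crop))  # SNR 10
  seg <- segment_cluster(crop)
  truth <- matrix(FALSE, nrow(crop), ncol(crop))
  truth[5:(4 + nrow(m)), 5:(4 + ncol(m))][m] <- TRUE
  iou <- sum(seg & truth) / sum(seg | truth)
  expect_gte(iou, 0.9)

  expect_warning(e <- segment_cluster(matrix(100, 16, 16),
                                      threshold = 1000), "empty")
  expect_false(any(e))
})

test_that("cluster measurements match the hull oracle on hard shapes", {
  disk <- make_disk(32)
  md <- measure_cluster(disk, 1)
  expect_equal(md$solidity, 1, tolerance = 0.01)
  expect_equal(md$area_um2, sum(disk))

  plus <- make_plus(arm = 6, pad = 3)
  mp <- measure_cluster(plus, 1)
  expect_equal(mp$solidity, oracle_solidity(plus), tolerance = 1e-9)
  expect_lt(mp$solidity, 1)

  for (s in c(0.9, 0.7, 0.5)) {
    m <- generate_cluster_mask(cluster_spec(10, s, 4, rng_seed = 4))
    expect_equal(measure_cluster(m, 0.045)$solidity, s, tolerance = 0.05)
  }
  expect_error(measure_cluster(matrix(FALSE, 4, 4), 1), "empty")
})

test_that("area is rotation invariant and perimeter/area scales as 1/s", {
  m <- generate_cluster_mask(cluster_spec(10, 0.7, 4, rng_seed = 6))
  a0 <- measure_cluster(m, 0.045)$area_um2
  for (k in 1:3) {
    mr <- m
    for (i in seq_len(k)) mr <- t(mr[nrow(mr):1, ])  # 90-degree rotation
    expect_equal(measure_cluster(mr, 0.045)$area_um2, a0)  # exact
  }
  # arbitrary-angle resample of a disk: area within 2%
  r <- 20
  big <- make_disk(r, 8)
  n <- nrow(big)
  th <- pi / 7
  c0 <- (n + 1) / 2
  rot <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in 1:n) {
    y <- c0 + cos(th) * (i - c0) - sin(th) * (j - c0)
    x <- c0 + sin(th) * (i - c0) + cos(th) * (j - c0)
    rot[i, j] <- (y - c0)^2 + (x - c0)^2 <= r^2
  }
  expect_equal(sum(rot), sum(big), tolerance = 0.02)

  # similar shapes: perimeter/area halves when the disk radius doubles
  poa <- vapply(c(16, 32), function(r)
    with(measure_cluster(make_disk(r), 1), perimeter_over_area_per_um),
    numeric(1))
  expect_equal(poa[1] / poa[2], 2, tolerance = 0.05)
})

test_that("en-face flagging discriminates flat from side-view clusters", {
  flat <- array(100, c(48, 48, 20))
  flat[20:28, 20:28, 10:11] <- 500   # 2 planes over ~9 px lateral
  fm <- matrix(FALSE, 48, 48); fm[20:28, 20:28] <- TRUE
  expect_true(flag_en_face(flat, fm, pixel_size_um = 1, z_step_um = 1))

  side <- array(100, c(48, 48, 24))
  side[22:23, 22:23, 2:21] <- 500    # 20 planes over 2 px lateral
  sm <- matrix(FALSE, 48, 48); sm[22:23, 22:23] <- TRUE
  expect_false(flag_en_face(side, sm, pixel_size_um = 1, z_step_um = 1))
})

test_that("generator-labeled orientations agree with the flag", {
  hits <- 0L
  n_try <- 20L
  for (s in seq_len(n_try)) {
    withr::with_seed(s, {
      flat_case <- s %% 2 == 0
      st <- array(round(rnorm(32 * 32 * 16, 100, 5)), c(32, 32, 16))
      if (flat_case) {
        st[10:24, 10:24, 8] <- 500
        mk <- matrix(FALSE, 32, 32); mk[10:24, 10:24] <- TRUE
      } else {
        st[15:17, 15:17, 2:15] <- 500
        mk <- matrix(FALSE, 32, 32); mk[15:17, 15:17] <- TRUE
      }
      got <- flag_en_face(st, mk, pixel_size_um = 0.3, z_step_um = 0.3)
      if (got == flat_case) hits <- hits + 1L
    })
  }
  expect_gte(hits / n_try, 0.9)
})
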