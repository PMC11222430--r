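test_that("positivity percentage follows the threshold rule", {
  lab <- matrix(0L, 20, 40)
  lab[3:6, 3:6] <- 1L
  lab[3:6, 13:16] <- 2L
  lab[13:16, 3:6] <- 3L
  lab[13:16, 13:16] <- 4L
  marker <- matrix(100, 20, 40)
  marker[lab %in% c(1L, 2L, 3L)] <- 500
  regions <- label_regions(lab, marker, 1)
  expect_equal(pct_positive_nuclei(regions, marker, 110), 75)
  expect_equal(pct_positive_nuclei(regions, marker, 600), 0)  # T above all
  none <- label_regions(matrix(0L, 20, 40), NULL, 1)
  expect_warning(p <- pct_positive_nuclei(none, marker, 110), "no nuclei")
  expect_true(is.na(p))
})

test_that("differentiation index equals the centroid-in-mask fraction", {
  lab <- matrix(0L, 40, 40)
  lab[2:6, 2:6] <- 1L
  lab[2:6, 12:16] <- 2L
  lab[12:16, 2:6] <- 3L
  lab[30:34, 30:34] <- 4L
  regions <- label_regions(lab, NULL, 1)
  mask <- matrix(FALSE, 40, 40)
  mask[1:20, 1:20] <- TRUE
  expect_equal(differentiation_index(regions, mask), 75)
  expect_equal(differentiation_index(regions, matrix(FALSE, 40, 40)), 0)
  # exhaustive oracle: per-nucleus point-in-mask on the same fixture
  set.seed(5)
  mask2 <- matrix(runif(1600) > 0.5, 40, 40)
  ids <- sort(unique(lab[lab > 0]))
  oracle <- mean(vapply(ids, function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    cy <- round(mean(idx[, 1] - 1)) + 1
    cx <- round(mean(idx[, 2] - 1)) + 1
    mask2[cy, cx]
  }, logical(1)))
  expect_equal(differentiation_index(regions, mask2), 100 * oracle)
})

test_that("MFI averages per-region means of positive regions", {
  lab <- matrix(0L, 10, 30)
  lab[2:5, 2:5] <- 1L
  lab[2:5, 12:15] <- 2L
  lab[2:5, 22:25] <- 3L
  marker <- matrix(50, 10, 30)
  marker[lab == 1L] <- 100
  marker[lab == 2L] <- 200
  regions <- label_regions(lab, marker, 1)
  expect_equal(mfi_positive(regions, marker, 60), 150)
  expect_warning(v <- mfi_positive(regions, marker, 300), "no positive")
  expect_true(is.na(v))
})

test_that("myonuclear domain is the exact quotient with its product invariant", {
  expect_equal(myonuclear_domain(10000, 20), 500)
  expect_equal(myonuclear_domain(0, 4), 0)
  expect_error(myonuclear_domain(100, 0), "zero")
  a <- myonuclear_domain(8123.77, 13)
  expect_equal(a * 13, 8123.77, tolerance = 1e-12)
})

test_that("cluster density and integrated density are exact arithmetic", {
  expect_equal(cluster_density(3, 1500), 2)
  expect_equal(cluster_density(0, 1500), 0)
  expect_error(cluster_density(3, 0), "zero")
  expect_equal(integrated_density(matrix(TRUE, 10, 10), matrix(10, 10, 10), 0.28),
               10 * 100 * 0.28^2)
  expect_equal(integrated_density(matrix(FALSE, 4, 4), matrix(5, 4, 4), 1), 0)
  # brute-force oracle on a random image/mask
  set.seed(9)
  img <- matrix(runif(64 * 64, 0, 500), 64, 64)
  mask <- matrix(runif(64 * 64) > 0.7, 64, 64)
  oracle <- 0
  for (i in 1:64) for (j in 1:64) if (mask[i, j]) oracle <- oracle + img[i, j]
  expect_equal(integrated_density(mask, img, 0.28), oracle * 0.0784)
})

test_that("percentages stay within [0, 100] on generated fields", {
  for (s in 1:3) {
    f <- generate_myotube_field(scene_spec(field_px = 256, n_nuclei = 20,
                                           marker_positive_fraction = runif(1),
                                           rng_seed = s))
    nuc <- segment_nuclei(f$image, "DAPI")
    myog <- get_channel(f$image, "MyoG")
    m <- estimate_background(myog)
    p <- pct_positive_nuclei(nuc, myog, m)
    d <- differentiation_index(nuc, f$truth$myotube_mask)
    expect_true(p >= 0 && p <= 100)
    expect_true(d >= 0 && d <= 100)
  }
})

test_that("full readout recovers generator truth on a clustered field", {
  cs <- lapply(1:4, function(i) cluster_spec(8, 0.9, 1, pixel_size_um = 0.28,
                                             rng_seed = i))
  f <- generate_myotube_field(scene_spec(field_px = 448, n_nuclei = 40,
                                         cluster_specs = cs, rng_seed = 17))
  ro <- myogenic_readout(f$image)
  expect_equal(ro$n_nuclei, f$truth$n_nuclei)
  expect_equal(ro$pct_myog_positive, f$truth$pct_positive, tolerance = 0.04)
  expect_equal(ro$total_muscle_area_um2, f$truth$muscle_area_um2,
               tolerance = 0.05)
  expect_equal(ro$n_clusters, 4L)
  true_density <- 1000 * 4 / f$truth$muscle_area_um2
  expect_equal(ro$cluster_density_per_1000um2, true_density, tolerance = 0.10)
  if (ro$n_myonuclei > 0)
    expect_equal(ro$mnd_area_um2 * ro$n_myonuclei, ro$total_muscle_area_um2)
})
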