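test_that("background model arithmetic matches its definition", {
  m <- estimate_background(matrix(10, 64, 64))
  expect_equal(m$mu, 10)
  expect_equal(m$sigma, 0)
  expect_equal(m$threshold, 10)

  # two explicit regions valued 8 and 12: mu 10, sigma pooled over pixels
  img <- matrix(0, 20, 20)
  img[1:4, 1:4] <- 8
  img[10:13, 10:13] <- 12
  m2 <- estimate_background(img, regions = list(c(1, 4, 1, 4), c(10, 13, 10, 13)))
  expect_equal(m2$mu, 10)
  expect_equal(m2$threshold, 10 + 2 * m2$sigma)
  expect_equal(m2$sigma, sd(c(rep(8, 16), rep(12, 16))))
})

test_that("auto-sampled background recovers generator noise statistics", {
  f <- generate_myotube_field(scene_spec(rng_seed = 13))
  m <- estimate_background(get_channel(f$image, "MyoG"))
  expect_equal(m$n_regions, 5L)
  expect_lt(abs(m$mu - 100), 1)
  expect_lt(abs(m$sigma - 5), 1)
})

test_that("positivity threshold is a strict inequality", {
  img <- matrix(c(15, 14, 13, 100), 2, 2)
  mask <- threshold_positive_mask(img, structure(
    list(mu = 10, sigma = 2, k = 2, threshold = 14), class = "background_model"))
  expect_true(mask[1, 1])   # 15 > 14
  expect_false(mask[2, 1])  # 14 is not > 14
  # enormous k empties the mask
  f <- matrix(rnorm(64, 100, 5), 8, 8)
  expect_false(any(threshold_positive_mask(f, max(f) + 1)))
})

test_that("positive-pixel counts match an exhaustive per-pixel oracle", {
  set.seed(42)
  img <- matrix(runif(64 * 64, 0, 200), 64, 64)
  m <- estimate_background(img, block = 8)
  mask <- threshold_positive_mask(img, m)
  oracle <- 0L
  for (i in 1:64) for (j in 1:64) if (img[i, j] > m$threshold) oracle <- oracle + 1L
  expect_equal(sum(mask), oracle)
})

test_that("increasing k never grows the positive mask", {
  set.seed(7)
  img <- matrix(rnorm(128 * 128, 100, 10), 128, 128)
  areas <- vapply(c(0.5, 1, 2, 3, 5), function(k)
    sum(threshold_positive_mask(img, estimate_background(img, k = k))),
    numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("debris filter deletes small AND round regions only", {
  ps <- 1
  lab <- matrix(0L, 80, 200)
  lab[10:31, 10:31] <- 1L       # ~484 um2 square, circularity ~0.78 -> deleted
  lab[40:42, 5:195] <- 2L       # 573 um2 elongated -> retained (big enough)
  lab[50:53, 10:109] <- 3L      # 400 um2 elongated, circ ~0.2 -> retained
  regions <- label_regions(lab, NULL, ps)
  expect_equal(n_regions(regions), 3L)
  tab <- regions$table
  expect_lt(tab$area_um2[1], 500)
  expect_true(tab$circularity[1] >= 0.3 && tab$circularity[1] <= 1)
  expect_lt(tab$circularity[3], 0.3)

  kept <- filter_debris(regions, debris_filter(min_area_um2 = 500))
  expect_equal(n_regions(kept), 2L)
  # relabeling preserves order and the map matches the table
  expect_equal(kept$table$label, 1:2)
  expect_equal(sort(unique(kept$labels[kept$labels > 0])), 1:2)

  # area-only mode also deletes the elongated small fragment
  kept2 <- filter_debris(regions, debris_filter(min_area_um2 = 500,
                                                mode = "area_only"))
  expect_equal(n_regions(kept2), 1L)
})

test_that("debris filtering equals brute-force predicate evaluation", {
  set.seed(3)
  img <- matrix(rnorm(128 * 128, 100, 5), 128, 128)
  for (i in 1:40) {
    cy <- sample(10:118, 1); cx <- sample(10:118, 1)
    r <- sample(2:9, 1)
    iy <- pmax(1, cy - r):pmin(128, cy + r)
    img[iy, pmax(1, cx - r):pmin(128, cx + r)] <- 400
  }
  ps <- 2.5
  lab <- EBImage::imageData(EBImage::bwlabel(img > 200))
  regions <- label_regions(lab, img, ps)
  filt <- debris_filter(min_area_um2 = 500)
  kept <- filter_debris(regions, filt)
  oracle_keep <- vapply(seq_len(nrow(regions$table)), function(i) {
    a <- regions$table$area_um2[i]
    c <- regions$table$circularity[i]
    !(a < 500 && c >= 0.3 && c <= 1.0)
  }, logical(1))
  expect_equal(n_regions(kept), sum(oracle_keep))
  expect_equal(kept$table$area_um2, regions$table$area_um2[oracle_keep])
})

test_that("nuclei segmentation recovers well-separated instances exactly", {
  f <- generate_myotube_field(scene_spec(field_px = 448, n_nuclei = 50,
                                         rng_seed = 21))
  nuc <- segment_nuclei(f$image, "DAPI")
  expect_equal(n_regions(nuc), 50L)

  blank <- matrix(round(rnorm(256^2, 100, 5)), 256, 256)
  nb <- segment_nuclei(blank, pixel_size = 0.28)
  expect_equal(n_regions(nb), 0L)
})

test_that("watershed splits touching nuclei", {
  img <- matrix(100, 96, 96)
  iy <- matrix(1:96, 96, 96); ix <- t(iy)
  # two disks tangent at one point
  img[(iy - 40)^2 + (ix - 48)^2 <= 12^2] <- 500
  img[(iy - 64)^2 + (ix - 48)^2 <= 12^2] <- 500
  nuc <- segment_nuclei(img, pixel_size = 0.28, min_area_um2 = 5)
  expect_equal(n_regions(nuc), 2L)
})

test_that("circularity of a large digital disk approaches 1", {
  lab <- matrix(0L, 73, 73)
  lab[make_disk(32, 4)] <- 1L
  tab <- measure_regions(lab, NULL, 1)
  expect_equal(tab$circularity, 1, tolerance = 0.05)
  expect_equal(tab$solidity, 1, tolerance = 0.01)
})

test_that("muscle segmentation recovers painted area within 5%", {
  f <- generate_myotube_field(scene_spec(rng_seed = 31))
  mus <- segment_muscle(f$image, "MYH1")
  expect_equal(mus$total_area_um2, f$truth$muscle_area_um2, tolerance = 0.05)
  # conservation: total equals the sum over the returned table
  expect_equal(mus$total_area_um2, sum(mus$regions$table$area_um2))

  blank <- matrix(round(rnorm(128^2, 100, 5)), 128, 128)
  mb <- segment_muscle(blank, pixel_size = 0.28)
  expect_equal(mb$total_area_um2, 0)
})
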