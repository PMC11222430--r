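pc_spec <- function(seed, density = 5)
  scene_spec(field_px = 96, pixel_size_um = 0.2, z_step_um = 0.5,
             puncta_density_true = density, rng_seed = seed)

test_that("crop window converts physical length and clamps at borders", {
  st <- array(seq_len(200 * 200 * 4), c(200, 200, 4))
  cr <- crop_around_cluster(st, c(100, 100, 2), length_um = 40,
                            pixel_size_um = 0.28)
  rng <- attr(cr, "crop_range")
  expect_equal(diff(rng) + 1, 2 * round(40 / 0.28 / 2) + 1)  # ~143 px
  # content equals direct slicing
  expect_equal(cr[, , ], st[, rng[1]:rng[2], ], ignore_attr = TRUE)

  expect_warning(cc <- crop_around_cluster(st, c(100, 10, 2), length_um = 40,
                                           pixel_size_um = 0.28), "clamped")
  expect_equal(attr(cc, "crop_range")[1], 1)
  expect_error(crop_around_cluster(st, c(100, 500, 2), length_um = 40,
                                   pixel_size_um = 0.28), "outside")
})

test_that("myotube volume is recovered within 10% and uses the calibration", {
  pc <- generate_pulse_chase_stack(pc_spec(5))
  vol <- segment_myotube_volume(pc$image)
  expect_equal(vol$volume_um3, pc$truth$volume_um3, tolerance = 0.10)
  # volume = voxel count x voxel volume at the imaging calibration
  expect_equal(vol$volume_um3, sum(vol$mask) * 0.2 * 0.2 * 0.5)
})

test_that("blank stacks raise a no-foreground error", {
  expect_error(segment_myotube_volume(array(100, c(16, 16, 8)),
                                      pixel_size_um = 0.045, z_step_um = 0.3),
               "foreground")
})

test_that("manual masks pass through with exact voxel arithmetic", {
  mask <- array(FALSE, c(10, 10, 6))
  mask[2:9, 2:9, 2:5] <- TRUE
  v <- segment_myotube_volume(array(100, c(10, 10, 6)), manual_mask = mask,
                              pixel_size_um = 0.045, z_step_um = 0.3)
  expect_equal(v$volume_um3, sum(mask) * 0.045^2 * 0.3)
})

test_that("puncta detection recovers planted counts", {
  pc0 <- generate_pulse_chase_stack(pc_spec(3, density = 0))
  vol0 <- segment_myotube_volume(pc0$image)
  d0 <- detect_puncta(pc0$image, vol0$mask, cluster_mask = pc0$truth$cluster_mask)
  expect_equal(d0$count, 0L)

  errs <- vapply(4:9, function(s) {
    pc <- generate_pulse_chase_stack(pc_spec(s))
    vol <- segment_myotube_volume(pc$image)
    d <- detect_puncta(pc$image, vol$mask, cluster_mask = pc$truth$cluster_mask)
    d$count - pc$truth$n_puncta
  }, numeric(1))
  expect_lte(max(abs(errs)), 1)
})

test_that("puncta density arithmetic and linearity hold", {
  expect_equal(puncta_density(5, 2500), 2)
  expect_equal(puncta_density(0, 2500), 0)
  expect_error(puncta_density(1, 0), "zero")

  dens <- vapply(c(4, 8), function(d) {
    counts <- vapply(1:4, function(s) {
      pc <- generate_pulse_chase_stack(pc_spec(100 + s, density = d))
      vol <- segment_myotube_volume(pc$image)
      detect_puncta(pc$image, vol$mask,
                    cluster_mask = pc$truth$cluster_mask)$count /
        vol$volume_um3 * 1000
    }, numeric(1))
    mean(counts)
  }, numeric(1))
  expect_equal(dens[2] / dens[1], 2, tolerance = 0.15)
})

test_that("size-window boundary semantics are inclusive keep bounds", {
  mk_comp <- function(n_vox, at, dims = c(60, 60, 40)) {
    # a 10 x 10 x ceiling slab trimmed to exactly n_vox voxels
    st <- array(FALSE, dims)
    nz <- ceiling(n_vox / 100)
    full <- st
    cnt <- 0
    for (z in seq_len(nz)) for (x in 1:10) for (y in 1:10) {
      if (cnt < n_vox) {
        full[at[1] + y, at[2] + x, at[3] + z] <- TRUE
        cnt <- cnt + 1
      }
    }
    full
  }
  st <- array(100, c(60, 60, 40))
  st[mk_comp(999, c(0, 0, 0))] <- 500
  st[mk_comp(1000, c(30, 30, 0))] <- 500
  p <- label_pipeline_params(opening_radius = 0, dilation_radius = 0,
                             final_dilation_radius = 0)
  r <- vacht_label_pipeline(st, p)
  expect_equal(r$sizes, 1000)
  expect_false(any(r$mask[1:20, 1:20, ]))     # 999-voxel component removed
  expect_true(any(r$mask[31:50, 31:50, ]))    # 1000-voxel component kept

  # upper bound via the filter directly (inclusive keep at 115000)
  lab <- array(0L, c(50, 50, 50))
  lab[1:46, 1:50, 1:50] <- 1L    # 115000
  lab[48:50, 1:50, 1:25] <- 2L   # 3750
  expect_equal(sort(unique(as.integer(
    filter_components_by_size(lab, 1000, 115000)))), c(0L, 1L, 2L))
  lab[48, 1, 26] <- 1L           # now 115001
  kept <- filter_components_by_size(lab, 1000, 115000)
  expect_false(any(kept[1:46, , ] > 0))
})

test_that("size filtering equals brute-force component enumeration", {
  withr::with_seed(11, {
    st <- array(runif(48^3) > 0.9, c(48, 48, 48))
    lab <- label_components_3d(st)
    win <- c(3, 40)
    kept <- filter_components_by_size(lab, win[1], win[2])
    for (id in seq_len(max(lab))) {
      n_vox <- sum(lab == id)
      inside <- n_vox >= win[1] && n_vox <= win[2]
      expect_equal(any(kept[lab == id] > 0), inside)
    }
    # kept components are renumbered consecutively
    ids <- sort(unique(kept[kept > 0]))
    expect_equal(ids, seq_along(ids))
  })
})

test_that("opening removes isolated voxels and the pipeline masks signal", {
  st <- array(100, c(32, 32, 32))
  st[4:23, 4:23, 4:13] <- 400      # 4000-voxel block survives the window
  st[28, 28, 28] <- 400            # isolated voxel
  r <- vacht_label_pipeline(st, label_pipeline_params())
  expect_false(r$mask[28, 28, 28])
  expect_true(any(r$mask[10:17, 10:17, 6:11]))
  expect_true(all(r$masked_signal[!r$mask] == 0))
  expect_true(all(r$masked_signal[r$mask] == st[r$mask]))

  # determinism: identical input, identical labels
  r2 <- vacht_label_pipeline(st, label_pipeline_params())
  expect_identical(r$labels, r2$labels)
})

test_that("opening then dilation never recreates an isolated voxel", {
  st <- array(FALSE, c(16, 16, 16))
  st[8, 8, 8] <- TRUE
  opened <- open_ball1_3d(st)
  expect_false(any(opened))
  expect_false(any(dilate_ball1_3d(opened)))
})
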