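test_that("field generation is deterministic and honors degenerate specs", {
  spec <- scene_spec(field_px = 192, n_nuclei = 15, rng_seed = 7)
  a <- generate_myotube_field(spec)
  b <- generate_myotube_field(spec)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth$nucleus_labels, b$truth$nucleus_labels)

  empty <- generate_myotube_field(scene_spec(field_px = 128, n_nuclei = 0,
                                             n_myotubes = 0, rng_seed = 1))
  expect_equal(empty$truth$n_nuclei, 0L)
  expect_true(all(empty$truth$nucleus_labels == 0))
  dapi <- get_channel(empty$image, "DAPI")
  expect_lt(abs(mean(dapi) - 100), 1)  # background only

  allpos <- generate_myotube_field(scene_spec(field_px = 256, n_nuclei = 40,
                                              marker_positive_fraction = 1,
                                              rng_seed = 3))
  expect_equal(sum(allpos$truth$nucleus_positive), 40L)
})

test_that("ground truth is self-consistent with the rendered scene", {
  f <- generate_myotube_field(scene_spec(field_px = 256, n_nuclei = 25,
                                         rng_seed = 11))
  tr <- f$truth
  expect_equal(tr$n_nuclei, max(tr$nucleus_labels))
  expect_equal(tr$muscle_area_um2, sum(tr$myotube_mask) * 0.28^2)
  expect_equal(tr$pct_in_muscle, 100 * mean(tr$in_muscle))
  # nucleus channel content: every labeled pixel is bright in DAPI
  dapi <- get_channel(f$image, "DAPI")
  expect_gt(min(dapi[tr$nucleus_labels > 0]), 300)
  expect_equal(dim(tr$nucleus_labels), dim(dapi))
})

test_that("overcrowded specs signal a placement failure", {
  expect_error(generate_myotube_field(scene_spec(field_px = 64, n_nuclei = 200,
                                                 rng_seed = 1)),
               "placement failure")
})

test_that("cluster masks meet solidity and area targets", {
  # convex single fragment: exact solidity 1
  m <- generate_cluster_mask(cluster_spec(10, 1, 1))
  expect_equal(oracle_solidity(m), 1, tolerance = 0.01)
  expect_equal(sum(m), 10 / 0.045^2, tolerance = 0.10)

  # fragmented: independent hull oracle confirms the achieved solidity
  m4 <- generate_cluster_mask(cluster_spec(10, 0.5, 4, rng_seed = 2))
  expect_equal(oracle_solidity(m4), 0.5, tolerance = 0.05)
  expect_equal(sum(m4) * 0.045^2, 10, tolerance = 0.10)

  expect_error(generate_cluster_mask(cluster_spec(10, 1, 4)), "infeasible")
})

test_that("calcium movies encode the stated transient exactly", {
  spec0 <- scene_spec(field_px = 48, pixel_size_um = 0.56, rng_seed = 1)
  # zero amplitude: all frames statistically identical to baseline
  mv0 <- generate_calcium_movie(spec0, transient_params(amplitude = 0,
                                                        noise_sd = 0))
  x <- get_channel(mv0$image, "Fluo4")
  expect_equal(max(x) - min(x), 0)
  expect_equal(mv0$truth$true_peak_dff, 0)

  # printed-formula arithmetic: F0 100, amplitude 50 -> (150-100)/150
  mv <- generate_calcium_movie(spec0, transient_params(f0 = 100, amplitude = 50,
                                                       noise_sd = 0))
  expect_equal(mv$truth$true_peak_dff, 1 / 3, tolerance = 1e-12)

  # two seeds differ only within the stated noise
  p <- transient_params(noise_sd = 4)
  m1 <- generate_calcium_movie(scene_spec(field_px = 48, rng_seed = 1), p)
  m2 <- generate_calcium_movie(scene_spec(field_px = 48, rng_seed = 2), p)
  d <- as.numeric(m1$image$data - m2$image$data)
  expect_equal(mean(d), 0, tolerance = 0.2)
  expect_equal(sd(d), sqrt(2) * 4, tolerance = 0.5)

  expect_error(transient_params(t_stim = 130, duration_s = 120), "duration")
})

test_that("pulse-chase stacks place puncta at the stated density", {
  base <- scene_spec(field_px = 96, pixel_size_um = 0.2, z_step_um = 0.5,
                     puncta_density_true = 0, rng_seed = 5)
  pc0 <- generate_pulse_chase_stack(base)
  expect_equal(pc0$truth$n_puncta, 0L)

  counts <- vapply(1:12, function(s) {
    sp <- scene_spec(field_px = 96, pixel_size_um = 0.2, z_step_um = 0.5,
                     puncta_density_true = 5, rng_seed = s)
    pc <- generate_pulse_chase_stack(sp)
    expect_equal(nrow(pc$truth$puncta_coords), pc$truth$n_puncta)
    pc$truth$n_puncta
  }, numeric(1))
  pc <- generate_pulse_chase_stack(scene_spec(field_px = 96, pixel_size_um = 0.2,
                                              z_step_um = 0.5, rng_seed = 1))
  lambda <- 5 * pc$truth$volume_um3 / 1000
  # Poisson mean recovery within 3 SE
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / length(counts)))

  # the two channels share identical calibration metadata
  expect_equal(pc$image$pixel_size, 0.2)
  expect_equal(pc$image$z_step, 0.5)
  expect_equal(pc$image$channels, c("old_label", "new_label"))
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(scene_spec(marker_positive_fraction = 1.5))
  expect_error(scene_spec(pixel_size_um = 0))
  expect_error(scene_spec(puncta_density_true = -1))
  expect_error(cluster_spec(0, 0.5))
  expect_error(cluster_spec(10, 0))
})
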