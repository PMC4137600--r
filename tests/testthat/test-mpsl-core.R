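test_that("dual-range masking takes the union of closed intervals", {
  arr <- array(c(-75, 300, -100, 200, -50, 50, 0, -1000), c(2, 2, 2))
  v <- phase_volume(arr, c(1, 1, 1))
  m <- build_mask(v, intensity_range(-100, 200), intensity_range(-50, 50))
  expect_identical(c(m$voxels),
                   c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  # disjoint ranges covering no voxel give an empty mask
  m2 <- build_mask(v, c(5000, 6000), c(7000, 8000))
  expect_equal(sum(m2$voxels), 0)
  # identical ranges reduce to single-range thresholding
  m3 <- build_mask(v, c(-50, 50), c(-50, 50))
  expect_identical(m3$voxels, arr >= -50 & arr <= 50)
  expect_error(intensity_range(10, -10), "lo <= hi")
})

test_that("threshold baseline keeps voxels strictly above the cutoff", {
  arr <- array(c(-1000, -83, -82.9, 500), c(2, 2, 1))
  v <- phase_volume(arr, c(1, 1, 1))
  m <- threshold_baseline(v, -83)
  expect_identical(c(m$voxels), c(FALSE, FALSE, TRUE, TRUE))
  u <- phase_volume(array(-1000, c(3, 3, 3)), c(1, 1, 1))
  expect_equal(sum(threshold_baseline(u)$voxels), 0)
})

test_that("the pipeline recovers a free-floating sphere and stays inside the threshold mask", {
  ph <- generate_phantom(phantom_spec(rng_seed = 42))
  v <- ph$series$phases[[1]]
  cfg <- mpsl_config()
  res <- segment_phase(v, cfg)
  m <- overlap_metrics(ph$truth_masks[[1]], res$gtv_mask)
  expect_gte(m$dice, 0.95)
  # stage monotonicity: final mask within the stage-1 threshold mask
  m0 <- build_mask(v, cfg$tumor_range, cfg$surround_range)
  expect_true(all(res$gtv_mask$voxels <= m0$voxels))
  expect_lte(res$diagnostics$n_eroded, res$diagnostics$n_mask)
  # the selected pre-dilation region volume respects the window
  sel <- res$candidate_table$regions
  selv <- sel$volume_cc[sel$label == res$selected_label]
  expect_true(selv >= cfg$volume_min_cc && selv <= cfg$volume_max_cc)
  # single connected component under the configured connectivity
  expect_equal(nrow(label_regions(res$gtv_mask, cfg$connectivity)$regions),
               1)
})

test_that("erosion severs a wall attachment that defeats plain thresholding", {
  spec <- phantom_suite(3)$wall_attached
  ph <- generate_phantom(spec)
  v <- ph$series$phases[[1]]
  # naive thresholding merges tumor and body into one region
  thr <- threshold_baseline(v, -83)
  expect_equal(nrow(label_regions(thr)$regions), 1)
  # MPSL separates and excludes the wall
  res <- segment_phase(v, mpsl_config())
  expect_gte(res$diagnostics$n_regions, 2)
  wall <- v$voxels > -400 & !ph$truth_masks[[1]]$voxels
  expect_equal(sum(res$gtv_mask$voxels & wall), 0)
  m <- overlap_metrics(ph$truth_masks[[1]], res$gtv_mask)
  expect_gte(m$dice, 0.95)
})

test_that("no surviving region raises a no-target failure with candidates", {
  v <- phase_volume(array(-1000, c(16, 16, 8)), c(2, 2, 2.5))
  err <- tryCatch(segment_phase(v, mpsl_config()),
                  mpsl_no_target_error = function(e) e)
  expect_s3_class(err$candidate_table, "region_table")
  # a volume window excluding the tumor also fails, carrying candidates
  ph <- generate_phantom(phantom_spec(rng_seed = 4,
                                      motion = list(type = "none")))
  cfg <- mpsl_config(volume_min_cc = 0.01, volume_max_cc = 0.05)
  err2 <- tryCatch(segment_phase(ph$series$phases[[1]], cfg),
                   mpsl_no_target_error = function(e) e)
  expect_gte(nrow(err2$candidate_table$regions), 1)
})

test_that("multiple survivors resolve to the largest with a warning", {
  fix <- two_sphere_series(n_phases = 1, amp_z = 0)
  v <- fix$series$phases[[1]]
  # enlarge one target so "largest" is well defined: shrink the window
  cfg <- mpsl_config(tumor_range = c(-100, 100),
                     surround_range = c(-100, 100), radius_mm = 3,
                     volume_min_cc = 0.1, volume_max_cc = 5)
  expect_warning(res <- segment_phase(v, cfg), "selecting the largest")
  expect_equal(res$diagnostics$n_survivors, 2)
})

test_that("seeded segmentation derives its range from the click neighborhood", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0,
                                      motion = list(type = "none")))
  v <- ph$series$phases[[1]]
  ctr <- round(dim(v$voxels) / 2)
  res <- segment_phase(v, mpsl_config(seed_point = ctr))
  m <- overlap_metrics(ph$truth_masks[[1]], res$gtv_mask)
  expect_gte(m$dice, 0.99)
  # seed in uniform lung background: degenerate band, no target
  expect_error(segment_phase(v, mpsl_config(seed_point = c(12, 32, 28))),
               class = "mpsl_no_target_error")
  # seed outside the volume bounds is a configuration error
  expect_error(segment_phase(v, mpsl_config(seed_point = c(999, 1, 1))),
               "outside the volume bounds")
})

test_that("with two survivors the seed picks its own region", {
  fix <- two_sphere_series(n_phases = 1, amp_z = 0)
  v <- fix$series$phases[[1]]
  seed_idx <- round(fix$static_center / c(2, 2, 2.5)) + 1L
  cfg <- mpsl_config(surround_range = c(-100, 100), radius_mm = 3,
                     volume_min_cc = 0.1, volume_max_cc = 5,
                     seed_point = seed_idx)
  res <- segment_phase(v, cfg)
  cog <- mask_cog(res$gtv_mask)
  expect_lt(sqrt(sum((cog - fix$static_center)^2)), 3)
})

test_that("seeded and unseeded runs agree when the seed lies in the unseeded mask", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0,
                                      motion = list(type = "none")))
  v <- ph$series$phases[[1]]
  r0 <- segment_phase(v, mpsl_config())
  seed <- round(mask_cog(r0$gtv_mask) / v$spacing) + 1L  # interior click
  expect_true(r0$gtv_mask$voxels[seed[1], seed[2], seed[3]])
  r1 <- segment_phase(v, mpsl_config(seed_point = seed))
  expect_identical(r0$gtv_mask$voxels, r1$gtv_mask$voxels)
})

test_that("segmentation is deterministic on identical input", {
  ph <- generate_phantom(phantom_spec(rng_seed = 13))
  v <- ph$series$phases[[3]]
  r1 <- segment_phase(v, mpsl_config())
  r2 <- segment_phase(v, mpsl_config())
  expect_identical(r1$gtv_mask$voxels, r2$gtv_mask$voxels)
})

test_that("successive localization tracks the moving target across phases", {
  fix <- two_sphere_series()
  seed_idx <- round(fix$mover_centers[1, ] / c(2, 2, 2.5)) + 1L
  cfg <- mpsl_config(surround_range = c(-100, 100), radius_mm = 3,
                     volume_min_cc = 0.1, volume_max_cc = 5,
                     seed_point = seed_idx, localization_margin_mm = 10)
  res <- segment_series(fix$series, cfg)
  expect_length(res, 10)
  for (k in 1:10) {
    cog <- mask_cog(res[[k]]$gtv_mask)
    expect_lt(sqrt(sum((cog - fix$mover_centers[k, ])^2)), 3)
    expect_false("localization_fallback" %in% res[[k]]$diagnostics$flags)
  }
})

test_that("a static series yields identical masks on every phase", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0,
                                      motion = list(type = "none")))
  res <- segment_series(ph$series, mpsl_config())
  for (k in 2:10)
    expect_identical(res[[k]]$gtv_mask$voxels, res[[1]]$gtv_mask$voxels)
})

test_that("per-phase failures carry the phase label", {
  ph <- generate_phantom(phantom_spec(rng_seed = 5))
  cfg <- mpsl_config(volume_min_cc = 0.001, volume_max_cc = 0.01)
  expect_error(segment_series(ph$series, cfg), "phase 0%")
})

test_that("2D mode segments slice-wise inside the threshold mask", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0,
                                      motion = list(type = "none")))
  v <- ph$series$phases[[1]]
  cfg <- mpsl_config(tumor_range = c(-10, 10), surround_range = c(-10, 10),
                     mode = "2d", volume_min_cc = 0.05, volume_max_cc = 12)
  res <- segment_phase(v, cfg)
  truth <- ph$truth_masks[[1]]
  expect_true(all(res$gtv_mask$voxels <= truth$voxels))
  m <- overlap_metrics(truth, res$gtv_mask)
  expect_gte(m$dice, 0.85)
})
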