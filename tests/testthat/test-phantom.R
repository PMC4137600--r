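test_that("phantom generation is seed-deterministic and phase-independent", {
  s <- phantom_spec(rng_seed = 7)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  for (k in 1:10)
    expect_identical(a$series$phases[[k]]$voxels,
                     b$series$phases[[k]]$voxels)
  # different seed changes the noise but not the truth
  c2 <- generate_phantom(phantom_spec(rng_seed = 8))
  expect_false(identical(a$series$phases[[1]]$voxels,
                         c2$series$phases[[1]]$voxels))
  expect_identical(a$truth_masks[[1]]$voxels, c2$truth_masks[[1]]$voxels)
})

test_that("a static noise-free phantom has ten identical phases", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0,
                                      motion = list(type = "none")))
  for (k in 2:10)
    expect_identical(ph$series$phases[[k]]$voxels,
                     ph$series$phases[[1]]$voxels)
  expect_equal(ph$truth_trajectory$volume_cc,
               rep(ph$truth_trajectory$volume_cc[1], 10))
})

test_that("sinusoidal motion spans twice the amplitude peak-to-peak", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0))
  z <- ph$truth_trajectory$cog_z_mm
  expect_equal(max(z) - min(z), 20)
  expect_equal(ph$truth_trajectory$cog_x_mm, rep(ph$spec$tumor_center_mm[1],
                                                 10))
  # truth volumes are constant under rigid motion (same voxel count up to
  # voxelization parity of the moving grid alignment)
  v <- ph$truth_trajectory$volume_cc
  expect_lt((max(v) - min(v)) / min(v), 0.01)
})

test_that("tissue intensities and ground truth are laid out as specified", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0,
                                      motion = list(type = "none")))
  v <- ph$series$phases[[1]]$voxels
  truth <- ph$truth_masks[[1]]$voxels
  expect_true(all(v[truth] == 0))              # virtual water tumor
  expect_true(any(v == -800))                  # lung background
  expect_true(any(v == 40))                    # body/wall shell
  expect_equal(v[1, 1, 1], -1000)              # air outside the body
  # truth volume close to the analytic 6-cm sphere
  expect_equal(sum(truth) * prod(c(2, 2, 2.5)) / 1000, 4 / 3 * pi * 27,
               tolerance = 0.02)
})

test_that("a tumor leaving the lung cavity is rejected with the phase named", {
  expect_error(
    generate_phantom(phantom_spec(
      motion = list(type = "sinusoid", amplitude_mm = c(0, 0, 40)))),
    "phase 0%")
  expect_error(
    generate_phantom(phantom_spec(tumor_diameter_mm = 120)),
    "does not fit")
})

test_that("the wall-neck attachment bridges tumor and chest wall", {
  ph <- generate_phantom(phantom_suite(1)$wall_attached)
  v <- ph$series$phases[[1]]
  # threshold mask over soft tissue is a single connected region
  m <- binary_mask(v$voxels > -400, v$spacing, v$origin)
  expect_equal(nrow(label_regions(m)$regions), 1)
  # the neck is part of the ground truth
  base <- generate_phantom(phantom_spec(motion = list(type = "none"),
                                        rng_seed = 1))
  expect_gt(sum(ph$truth_masks[[1]]$voxels),
            sum(base$truth_masks[[1]]$voxels))
})

test_that("custom displacement lists are honored exactly", {
  d <- cbind(0, 0, seq(0, 9))
  ph <- generate_phantom(phantom_spec(noise_sd = 0,
                                      motion = list(type = "custom",
                                                    displacements_mm = d)))
  ctr <- ph$spec$tumor_center_mm
  expect_equal(ph$truth_trajectory$cog_z_mm, ctr[3] + seq(0, 9))
})

test_that("write_phantom produces the full file inventory", {
  td <- withr::local_tempdir()
  ph <- generate_phantom(phantom_spec(dims = c(24, 24, 16), rng_seed = 3,
                                      tumor_diameter_mm = 20,
                                      motion = list(type = "none")))
  write_phantom(ph, td)
  expect_length(list.files(td, pattern = "^phase_.*nii"), 10)
  expect_length(list.files(td, pattern = "^truth_.*nii"), 10)
  expect_true(file.exists(file.path(td, "truth_trajectory.csv")))
  expect_true(file.exists(file.path(td, "phantom_spec.json")))
  # masks on disk reproduce the in-memory truth
  m <- read_mask(file.path(td, "truth_00.nii.gz"))
  expect_identical(m$voxels, ph$truth_masks[[1]]$voxels)
})
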