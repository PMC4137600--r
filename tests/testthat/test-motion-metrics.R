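sphere_array <- function(dims, spacing, center, r) {
  x <- (seq_len(dims[1]) - 1) * spacing[1]
  y <- (seq_len(dims[2]) - 1) * spacing[2]
  z <- (seq_len(dims[3]) - 1) * spacing[3]
  outer(outer((x - center[1])^2, (y - center[2])^2, `+`),
        (z - center[3])^2, `+`) <= r^2
}

test_that("COG and volume of a voxelized sphere match the analytic values", {
  sp <- c(1, 1, 1)
  dims <- c(70, 70, 70)
  ctr <- c(34.5, 34.5, 34.5)
  m <- binary_mask(sphere_array(dims, sp, ctr, 30), sp)
  cog <- mask_cog(m)
  expect_lt(max(abs(cog - ctr)), 0.5)  # within half a voxel
  # 6-cm sphere at 1 mm isotropic: within 2% of 4/3*pi*3^3 = 113.10 cc
  expect_equal(volume_cc(m), 4 / 3 * pi * 27, tolerance = 0.02)
  # translating the sphere translates the COG by the same vector
  m2 <- binary_mask(sphere_array(dims, sp, ctr + c(0, 0, 5), 30), sp)
  expect_equal(mask_cog(m2) - cog, c(0, 0, 5), tolerance = 0.01)
})

test_that("overlap metrics reproduce hand-computed counts and conventions", {
  sp <- c(1, 1, 1)
  base <- array(FALSE, c(4, 4, 2))
  truth <- base; truth[1:3, 1:2, 1] <- TRUE          # 6 voxels
  test <- base; test[2:3, 1:2, 1] <- FALSE
  test[2:4, 1, 1] <- TRUE; test[2, 2, 1] <- TRUE     # 4 voxels, 3 overlap
  m <- overlap_metrics(binary_mask(truth, sp), binary_mask(test, sp))
  expect_equal(m$n_truth, 6); expect_equal(m$n_test, 4)
  expect_equal(m$n_intersect, 3)
  expect_equal(m$dice, 0.6)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$ppv, 0.75)
  # identity and disjoint cases
  mi <- overlap_metrics(binary_mask(truth, sp), binary_mask(truth, sp))
  expect_equal(c(mi$dice, mi$sensitivity, mi$ppv), c(1, 1, 1))
  other <- base; other[4, 4, 2] <- TRUE
  md <- overlap_metrics(binary_mask(truth, sp), binary_mask(other, sp))
  expect_equal(c(md$dice, md$sensitivity, md$ppv), c(0, 0, 0))
  # both-empty and one-empty conventions
  e <- binary_mask(base, sp)
  me <- overlap_metrics(e, e)
  expect_equal(c(me$dice, me$sensitivity, me$ppv), c(1, 1, 1))
  mo <- overlap_metrics(binary_mask(truth, sp), e)
  expect_equal(c(mo$dice, mo$sensitivity, mo$ppv), c(0, 0, 0))
  expect_error(overlap_metrics(binary_mask(truth, sp),
                               binary_mask(array(FALSE, c(5, 4, 2)), sp)),
               "different grids")
})

test_that("metric identities hold on random mask pairs", {
  set.seed(21)
  for (i in 1:20) {
    a <- random_mask(c(8, 8, 5), p = stats::runif(1, 0.1, 0.6))
    b <- random_mask(c(8, 8, 5), p = stats::runif(1, 0.1, 0.6))
    mab <- overlap_metrics(a, b)
    mba <- overlap_metrics(b, a)
    expect_equal(mab$dice, mba$dice)                  # symmetry
    expect_equal(mab$sensitivity, mba$ppv)            # role swap
    expect_equal(mab$ppv, mba$sensitivity)
    if (mab$n_truth + mab$n_test > 0) {               # count consistency
      expect_equal(mab$dice,
                   2 * mab$n_intersect / (mab$n_truth + mab$n_test))
      if (mab$n_truth > 0)
        expect_equal(mab$sensitivity, mab$n_intersect / mab$n_truth)
      if (mab$n_test > 0)
        expect_equal(mab$ppv, mab$n_intersect / mab$n_test)
    }
    expect_true(all(c(mab$dice, mab$sensitivity, mab$ppv) >= 0))
    expect_true(all(c(mab$dice, mab$sensitivity, mab$ppv) <= 1))
  }
})

test_that("metrics_table appends Average and St.dev. rows", {
  sp <- c(1, 1, 1)
  mk <- function(n) {
    a <- array(FALSE, c(4, 4, 4)); a[seq_len(n)] <- TRUE
    binary_mask(a, sp)
  }
  pairs <- list(list(case_id = "a", truth = mk(8), test = mk(8)),
                list(case_id = "b", truth = mk(8), test = mk(4)),
                list(case_id = "c", truth = mk(6), test = mk(2)))
  tab <- metrics_table(pairs)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$case_id[4:5], c("Average", "St.dev."))
  hand <- c(1, 2 * 4 / 12, 2 * 2 / 8)
  expect_equal(tab$dice[1:3], hand)
  expect_equal(tab$dice[4], mean(hand))
  expect_equal(tab$dice[5], sd(hand))
  # single pair: mean = the pair, SD reported 0 with flag
  t1 <- metrics_table(pairs[1])
  expect_equal(t1$dice[2], 1)
  expect_equal(t1$dice[3], 0)
  expect_true(attr(t1, "sd_undefined"))
  # identical pairs: SD exactly 0
  t2 <- metrics_table(pairs[c(1, 1)])
  expect_equal(t2$dice[4], 0)
})

test_that("trajectory errors follow the displacement-from-phase-0 convention", {
  tr <- function(zs, vols) {
    structure(data.frame(phase = seq(0, by = 10, length.out = length(zs)),
                         cog_x_mm = 0, cog_y_mm = 0, cog_z_mm = zs,
                         volume_cc = vols),
              class = c("trajectory", "data.frame"), spacing = c(1, 1, 1))
  }
  truth <- tr(c(0, 5, 10), c(100, 100, 100))
  # identical trajectories: zero errors everywhere
  te0 <- trajectory_error(truth, truth)
  expect_equal(te0$rel_vol_err, c(0, 0, 0))
  expect_equal(te0$abs_disp_err_mm, c(0, 0, 0))
  # 105 vs 100 cc is a 5% volume error
  est <- tr(c(0, 5.5, 10), c(105, 100, 100))
  te <- trajectory_error(est, truth)
  expect_equal(te$rel_vol_err[1], 0.05)
  expect_equal(te$rel_disp_err[2], 0.5 / 5)
  expect_true(te$below_eps[1])        # phase 0 displacement is always 0
  expect_true(is.na(te$rel_disp_err[1]))
  # static truth: every phase flagged, absolute error still reported
  ts <- trajectory_error(tr(c(0, 1, 0), c(1, 1, 1)),
                         tr(c(0, 0, 0), c(1, 1, 1)))
  expect_true(all(ts$below_eps))
  expect_equal(ts$abs_disp_err_mm[2], 1)
  expect_error(
    trajectory_error(truth, tr(c(0, 5), c(1, 1))),
    "phase labels")
})

test_that("compute_trajectory reports one row per phase and fails on empty masks", {
  ph <- generate_phantom(phantom_spec(rng_seed = 2))
  traj <- compute_trajectory(ph$truth_masks)
  expect_equal(nrow(traj), 10)
  expect_equal(traj$phase, seq(0, 90, 10))
  # truth masks are voxelized spheres at analytic centers
  expect_equal(traj$cog_z_mm, ph$truth_trajectory$cog_z_mm, tolerance = 0.01)
  empty <- binary_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  expect_error(compute_trajectory(list(ph$truth_masks[[1]], empty)),
               "phase 10")
})
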