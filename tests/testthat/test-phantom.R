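small_spec <- function(laterality = "right") {
  phantom_spec(shape = c(48, 48, 24), spacing = c(1.5, 1.5, 1.2),
               laterality = laterality,
               tibia_radius = 20, tibia_height = 8, plateau_z = -3,
               menisci = list(
                 MM = list(center_offset = 12, r_inner = 3.5, r_outer = 7,
                           span_deg = 300, thickness = 3),
                 LM = list(center_offset = 12, r_inner = 3, r_outer = 6,
                           span_deg = 250, thickness = 3)))
}

test_that("phantom generation is deterministic per seed", {
  a <- make_phantom(small_spec(), seed = 7)
  b <- make_phantom(small_spec(), seed = 7)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$MM$data, b$MM$data)
  c <- make_phantom(small_spec(), seed = 8)
  expect_false(identical(a$volume$data, c$volume$data))
  # masks are noise-free geometry: identical across seeds
  expect_identical(a$MM$data, c$MM$data)
})

test_that("crescent voxel count matches the analytic sector volume", {
  ph <- make_phantom(phantom_spec(), seed = 1)
  vv <- voxel_volume(ph$volume)
  for (m in c("MM", "LM")) {
    g <- phantom_spec()$menisci[[m]]
    vol_analytic <- (g$span_deg / 360) * pi * (g$r_outer^2 - g$r_inner^2) *
      g$thickness
    expect_lt(abs(sum(ph[[m]]$data) * vv - vol_analytic) / vol_analytic, 0.05)
  }
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(menisci = list(
    MM = list(center_offset = 13, r_inner = 4.5, r_outer = 9,
              span_deg = 360, thickness = 3.5),
    LM = list(center_offset = 13, r_inner = 4, r_outer = 8,
              span_deg = 250, thickness = 3.5))), "span")
  expect_error(phantom_spec(shape = c(32, 32, 32), spacing = c(0.5, 0.5, 0.5),
                            menisci = list(
                              MM = list(center_offset = 13, r_inner = 4.5,
                                        r_outer = 9, span_deg = 300,
                                        thickness = 3.5),
                              LM = list(center_offset = 13, r_inner = 4,
                                        r_outer = 8, span_deg = 250,
                                        thickness = 3.5))), "margin|fit")
})

test_that("identity motion leaves the phantom unchanged with a zero field", {
  ph <- make_phantom(small_spec(), seed = 2)
  mv <- apply_motion(ph, ground_truth_motion())
  expect_equal(max(abs(mv$truth_field$u)), 0)
  expect_equal(mv$volume$data, ph$volume$data, tolerance = 1e-9)
  expect_identical(mv$MM$data, ph$MM$data)
})

test_that("a pure global translation gives a constant truth field", {
  ph <- make_phantom(small_spec(), seed = 2)
  mv <- apply_motion(ph, ground_truth_motion(
    global_rigid = rigid_transform(translation = c(2, -1, 0.5))))
  u <- mv$truth_field$u
  expect_equal(max(abs(sweep(u, 2, c(2, -1, 0.5), "-"))), 0, tolerance = 1e-9)
  # and the moving tibia mask is the template tibia shifted accordingly
  back <- resample(mv$tibia, rigid_transform(translation = c(2, -1, 0.5)),
                   "nearest", grid = ph$volume)
  expect_gt(dice_coef(ph$tibia, back), 0.95)
})

test_that("tibial rotation displaces by the chord length", {
  ph <- make_phantom(small_spec(), seed = 2)
  mv <- apply_motion(ph, ground_truth_motion(tibial_rotation_deg = 10))
  z0 <- ph$spec$plateau_z
  X <- grid_world_coords(ph$volume)
  # voxel ~20 mm from the rotation centre, in the rotation plane
  i <- which.min((X[, 1] - 20)^2 + X[, 2]^2 + (X[, 3] - z0)^2)
  r <- sqrt(sum(X[i, 1:2]^2))
  expect_equal(sqrt(sum(mv$truth_field$u[i, ]^2)),
               2 * r * sin(5 * pi / 180), tolerance = 1e-6)
})

test_that("in-plane meniscal translations move exactly the menisci", {
  ph <- make_phantom(small_spec(), seed = 2)
  mv <- apply_motion(ph, ground_truth_motion(
    meniscus_translation = list(MM = c(1.5, -2, 0), LM = c(-1, 2.5, 0)),
    window_width = 9))  # support < inter-meniscus gap: no cross-talk
  u <- mv$truth_relative$u
  idx_mm <- which(ph$MM$data > 0.5)
  idx_lm <- which(ph$LM$data > 0.5)
  idx_tib <- which(ph$tibia$data > 0.5)
  expect_equal(max(abs(sweep(u[idx_mm, ], 2, c(1.5, -2, 0), "-"))), 0,
               tolerance = 1e-9)
  expect_equal(max(abs(sweep(u[idx_lm, ], 2, c(-1, 2.5, 0), "-"))), 0,
               tolerance = 1e-9)
  expect_equal(max(abs(u[idx_tib, ])), 0, tolerance = 1e-9)
  expect_error(ground_truth_motion(
    meniscus_translation = list(MM = c(0, 0, 1), LM = c(0, 0, 0))),
    "in-plane")
  expect_error(ground_truth_motion(bump = list(center = c(0, 0, 0), width = 2,
                                               amplitude = c(9, 0, 0))),
               "8 mm|invertible")
})

test_that("warping the moving mask back through the truth field recovers
           the template mask", {
  # full default resolution: the masks must be several voxels thick for a
  # Dice-based roundtrip to be meaningful (the moving scan is re-rendered
  # and re-quantised in its new position)
  ph <- make_phantom(phantom_spec(), seed = 3)
  mv <- apply_motion(ph, ground_truth_motion(
    global_rigid = rigid_transform(angles = c(0, 0, 0.03),
                                   translation = c(1, -1, 0.5)),
    tibial_rotation_deg = 6,
    meniscus_translation = list(MM = c(1, -2, 0), LM = c(-1, 2, 0)),
    window_width = 9))
  for (m in c("MM", "LM")) {
    # soft (trilinear) resampling of the indicator with a 0.5 threshold:
    # nearest-neighbour would stack two half-voxel quantisations
    soft <- knee_volume(mv[[m]]$data, mv[[m]]$spacing, mv[[m]]$origin,
                        mv[[m]]$orientation)
    back <- resample(soft, mv$truth_field, "trilinear")
    expect_gt(dice_coef(ph[[m]],
                        list(data = (back$data >= 0.5) * 1)), 0.95)
  }
})

test_that("analytic ground truth agrees with crop_field + segment_motion
           on the truth field", {
  ph <- make_phantom(small_spec(), seed = 4)
  motion <- ground_truth_motion(
    tibial_rotation_deg = 5,
    meniscus_translation = list(MM = c(0.5, -1.5, 0), LM = c(-0.8, 2, 0)),
    window_width = 9)
  mv <- apply_motion(ph, motion)
  axes <- anatomical_axes(ph$MM, ph$LM, "right")
  labels <- list(MM = partition_arch(ph$MM, axes),
                 LM = partition_arch(ph$LM, axes))
  gt <- ground_truth_segment_motion(ph, motion, labels, axes)
  for (m in c("MM", "LM")) {
    sm <- segment_motion(mv$truth_relative, labels[[m]], axes, m)
    ref <- gt[gt$meniscus == m, ]
    expect_equal(sm$avg_mm, ref$avg_mm, tolerance = 1e-6)
    expect_equal(sm$ml_mm, ref$ml_mm, tolerance = 1e-6)
    expect_equal(sm$ap_mm, ref$ap_mm, tolerance = 1e-6)
  }
})

test_that("cohort simulation: zero SDs give identical draws equal to the
           means; seeded draws match within sampling error", {
  gen0 <- list(internal = list(
    MM = list(ml = c(0.5, 0), ap = c(-1.5, 0)),
    LM = list(ml = c(-1, 0), ap = c(4, 0)),
    rotation_deg = c(5, 0)))
  cs <- cohort_spec(n_subjects = 2, conditions = gen0,
                    rigid_angle_sd_deg = 0, rigid_trans_sd_mm = 0,
                    phantom = small_spec(), window_width = 9, seed = 5)
  sim <- simulate_cohort(cs, out_dir = withr::local_tempdir())
  whole <- sim$truth[sim$truth$segment == "whole", ]
  mm <- whole[whole$meniscus == "MM", ]
  expect_equal(mm$ml_mm, rep(0.5, 2), tolerance = 1e-6)
  expect_equal(mm$ap_mm, rep(-1.5, 2), tolerance = 1e-6)

  expect_error(cohort_spec(n_subjects = 1), "n_subjects")
  gen_bad <- gen0
  gen_bad$internal$MM$ml <- c(0.5, -1)
  expect_error(cohort_spec(conditions = gen_bad), "non-negative")
})

test_that("cohort draws follow the generating distribution", {
  gen <- list(internal = list(
    MM = list(ml = c(0.2, 0.4), ap = c(-1.7, 0.8)),
    LM = list(ml = c(-0.8, 0.4), ap = c(3.0, 0.6)),
    rotation_deg = c(8, 2)))
  cs <- cohort_spec(n_subjects = 10, conditions = gen,
                    phantom = small_spec(), window_width = 10, seed = 11)
  sim <- simulate_cohort(cs, out_dir = withr::local_tempdir())
  whole <- sim$truth[sim$truth$segment == "whole" &
                       sim$truth$meniscus == "LM", ]
  expect_lt(abs(mean(whole$ap_mm) - 3.0), 2 * 0.6 / sqrt(10) + 0.1)
  # file layout written
  expect_true(file.exists(file.path(sim$dir, "subject_01", "internal",
                                    "volume.nii.gz")))
  expect_true(file.exists(file.path(sim$dir, "subject_01", "meta.yaml")))
})
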