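ellipsoid_mask <- function(grid, center, semi) {
  X <- grid_world_coords(grid)
  m <- (X[, 1] - center[1])^2 / semi[1]^2 +
    (X[, 2] - center[2])^2 / semi[2]^2 +
    (X[, 3] - center[3])^2 / semi[3]^2 <= 1
  label_mask(array(as.numeric(m), dim(grid$data)), grid$spacing, grid$origin,
             grid$orientation)
}

test_that("crop_field restricts the field to the mask, unmodified", {
  d <- c(10, 10, 6)
  g <- centred_grid(d)
  m <- array(0, d); m[3:4, 5, 2:6] <- 1  # 10 voxels
  mask <- label_mask(m, g$spacing, g$origin)
  u <- matrix(rep(c(1, 2, 3), each = prod(d)), ncol = 3)
  out <- crop_field(deformation_field(u, g), mask)
  expect_equal(nrow(out), 10L)
  expect_true(all(out$ux == 1 & out$uy == 2 & out$uz == 3))

  # zero field restricted anywhere is zero
  z <- crop_field(deformation_field(matrix(0, prod(d), 3), g), mask)
  expect_true(all(z$ux == 0 & z$uy == 0 & z$uz == 0))
  empty <- label_mask(array(0, d), g$spacing, g$origin)
  expect_error(crop_field(deformation_field(u, g), empty), "empty")
})

test_that("anatomical axes follow the inter-meniscus direction and
           laterality", {
  g <- centred_grid(c(40, 40, 20))
  mm <- ellipsoid_mask(g, c(-9, 0, 0), c(5, 7, 2))
  lm <- ellipsoid_mask(g, c(9, 0, 0), c(5, 7, 2))
  ax <- anatomical_axes(mm, lm, "right")
  # ML axis within 2 degrees of the centroid-difference direction (+x)
  expect_gt(sum(ax$ml_axis * c(1, 0, 0)), cos(2 * pi / 180))
  # AP axis orthogonal, in-plane, pointing posterior (-y)
  expect_lt(abs(sum(ax$ml_axis * ax$ap_axis)), 1e-8)
  expect_gt(sum(ax$ap_axis * c(0, -1, 0)), 0.99)
  expect_equal(sqrt(sum(ax$ml_axis^2)), 1, tolerance = 1e-10)

  # mirrored configuration (left knee): ML flips so "lateral" stays
  # correct, AP is unchanged
  ax2 <- anatomical_axes(lm, mm, "left")  # menisci swap sides
  expect_gt(sum(ax2$ml_axis * c(-1, 0, 0)), cos(2 * pi / 180))
  expect_equal(ax2$ap_axis, ax$ap_axis, tolerance = 1e-6)

  # wrong laterality flag for the geometry warns
  expect_warning(anatomical_axes(mm, lm, "left"), "lateral")
})

test_that("spherical masks at the same centroid are degenerate", {
  g <- centred_grid(c(30, 30, 30))
  s1 <- ellipsoid_mask(g, c(0, 0, 0), c(6, 6, 6))
  expect_error(anatomical_axes(s1, s1, "right"), "degenerate|orthogonal")
})

test_that("a 180-degree crescent is cut at the 60/120-degree marks", {
  d <- c(64, 64, 10)
  g <- centred_grid(d)
  tm <- crescent_mask(g, r_in = 18, r_out = 24, span_deg = 180, zh = 2)
  pa <- partition_arch(tm, world_axes())
  X <- grid_world_coords(g)
  idx <- which(tm$data > 0.5)
  # construction angle from the arch start (0..180)
  ca <- (atan2(X[idx, 2], X[idx, 1])) * 180 / pi
  segs <- pa$data[idx]
  lo_seg <- segs[which.min(ca)]; hi_seg <- segs[which.max(ca)]
  b1 <- (max(ca[segs == lo_seg]) + min(ca[segs == 2])) / 2
  b2 <- (max(ca[segs == 2]) + min(ca[segs == hi_seg])) / 2
  expect_lt(abs(b1 - 60), 6)
  expect_lt(abs(b2 - 120), 6)
  # partition property: disjoint + exhaustive
  expect_equal(sum(pa$data > 0), length(idx))
  expect_true(all(pa$data[idx] %in% 1:3))
  # arc-length shares close to 1/3
  expect_true(all(abs(as.numeric(table(segs)) / length(idx) - 1 / 3) < 0.05))
})

test_that("a 300-degree crescent is cut into three 100-degree parts", {
  d <- c(64, 64, 10)
  g <- centred_grid(d)
  tm <- crescent_mask(g, r_in = 18, r_out = 24, span_deg = 300, zh = 2)
  pa <- partition_arch(tm, world_axes())
  X <- grid_world_coords(g)
  idx <- which(tm$data > 0.5)
  ca <- ((atan2(X[idx, 2], X[idx, 1]) - (90 - 150) * pi / 180) %% (2 * pi)) *
    180 / pi
  segs <- pa$data[idx]
  for (s in 1:3) {
    width <- diff(range(ca[segs == s]))
    expect_lt(abs(width - 100), 6)
  }
})

test_that("AH is the more anterior end and labelling is deterministic", {
  d <- c(64, 64, 10)
  g <- centred_grid(d)
  # asymmetric crescent: one end clearly anterior (low AP), the other
  # posterior, so the AH/PH assignment is unambiguous
  tm <- crescent_mask(g, r_in = 14, r_out = 20, span_deg = 200,
                      mid_deg = -60, zh = 2)
  ax <- world_axes()
  pa <- partition_arch(tm, ax)
  X <- grid_world_coords(g)
  idx <- which(tm$data > 0.5)
  ap <- as.numeric(sweep(X[idx, , drop = FALSE], 2,
                         colMeans(X[idx, , drop = FALSE]), "-") %*% ax$ap_axis)
  # mean AP of AH must be below (more anterior than) mean AP of PH
  expect_lt(mean(ap[pa$data[idx] == 1]), mean(ap[pa$data[idx] == 3]))
  # rerun is identical (deterministic, order-invariant input)
  pa2 <- partition_arch(tm, ax)
  expect_identical(pa$data, pa2$data)
})

test_that("closed annuli and disconnected masks are rejected", {
  g <- centred_grid(c(48, 48, 8))
  ring <- crescent_mask(g, r_in = 12, r_out = 18, span_deg = 359.9, zh = 1)
  expect_error(partition_arch(ring, world_axes()), "annulus|gap")
  two <- crescent_mask(g, r_in = 12, r_out = 18, span_deg = 60, zh = 1)
  two$data <- pmin(two$data +
                     crescent_mask(g, r_in = 12, r_out = 18, span_deg = 60,
                                   mid_deg = 270, zh = 1)$data, 1)
  expect_error(partition_arch(two, world_axes()), "disconnected")
})

test_that("segment motion projects constant fields with the Table-1 sign
           convention", {
  d <- c(48, 48, 12)
  g <- centred_grid(d)
  tm <- crescent_mask(g, r_in = 8, r_out = 14, span_deg = 240, zh = 2)
  ax <- world_axes()
  labs <- partition_arch(tm, ax)
  n <- prod(d)

  # 2 mm along the AP axis: avg 2, ml 0, ap +2 in every segment
  u_ap <- matrix(rep(2 * ax$ap_axis, each = n), ncol = 3)
  sm <- segment_motion(deformation_field(u_ap, g), labs, ax, "MM")
  expect_equal(sm$avg_mm, rep(2, 4), tolerance = 1e-12)
  expect_equal(sm$ml_mm, rep(0, 4), tolerance = 1e-12)
  expect_equal(sm$ap_mm, rep(2, 4), tolerance = 1e-12)

  # 2 mm against the ML axis: ml -2 (medial), ap 0, avg 2
  u_med <- matrix(rep(-2 * ax$ml_axis, each = n), ncol = 3)
  sm2 <- segment_motion(deformation_field(u_med, g), labs, ax, "LM")
  expect_equal(sm2$ml_mm, rep(-2, 4), tolerance = 1e-12)
  expect_equal(sm2$ap_mm, rep(0, 4), tolerance = 1e-12)
  expect_equal(sm2$avg_mm, rep(2, 4), tolerance = 1e-12)
})

test_that("a rigid in-plane rotation field reproduces the analytic
           segment-centroid displacements", {
  d <- c(48, 48, 12)
  g <- centred_grid(d)
  tm <- crescent_mask(g, r_in = 8, r_out = 14, span_deg = 240, zh = 2)
  ax <- world_axes()
  labs <- partition_arch(tm, ax)
  X <- grid_world_coords(g)
  th <- 10 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  u <- X %*% t(R) - X  # rotation about the plateau centre (origin)
  sm <- segment_motion(deformation_field(u, g), labs, ax, "MM")
  for (i in seq_len(nrow(sm))) {
    seg <- sm$segment[i]
    idx <- if (seg == "whole") which(labs$data > 0)
           else which(labs$data == match(seg, c("AH", "IH", "PH")))
    cen <- colMeans(X[idx, , drop = FALSE])
    truth <- as.numeric(R %*% cen - cen)
    expect_lt(abs(sm$avg_mm[i] - sqrt(sum(truth^2))),
              0.05 * max(sqrt(sum(truth^2)), 1e-9))
    expect_lt(abs(sm$ml_mm[i] - sum(truth * ax$ml_axis)), 0.05 * sm$avg_mm[i])
    expect_lt(abs(sm$ap_mm[i] - sum(truth * ax$ap_axis)), 0.05 * sm$avg_mm[i])
  }
})

test_that("whole-meniscus mean is the voxel-weighted mean of segments and
           projections are basis-independent", {
  set.seed(8)
  d <- c(40, 40, 10)
  g <- centred_grid(d)
  tm <- crescent_mask(g, r_in = 7, r_out = 12, span_deg = 250, zh = 2)
  ax <- world_axes()
  labs <- partition_arch(tm, ax)
  X <- grid_world_coords(g)
  u <- cbind(sin(X[, 1] / 5), cos(X[, 2] / 4), 0.3 * sin(X[, 3]))
  sm <- segment_motion(deformation_field(u, g), labs, ax, "MM")
  segs <- sm[sm$segment != "whole", ]
  whole <- sm[sm$segment == "whole", ]
  expect_equal(whole$n_voxels, sum(segs$n_voxels))
  expect_equal(whole$ml_mm,
               sum(segs$ml_mm * segs$n_voxels) / sum(segs$n_voxels),
               tolerance = 1e-10)
  expect_equal(whole$ap_mm,
               sum(segs$ap_mm * segs$n_voxels) / sum(segs$n_voxels),
               tolerance = 1e-10)
  # out-of-plane component is non-negative
  expect_true(all(sm$ml_mm^2 + sm$ap_mm^2 <= sm$avg_mm^2 + 1e-9))

  # rotating grid and axes together leaves (avg, ml, ap) unchanged
  th <- 0.4
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  g2 <- knee_volume(array(0, d), g$spacing, as.numeric(R %*% g$origin), R)
  tm2 <- label_mask(tm$data, g$spacing, g2$origin, R)
  labs2 <- knee_volume(labs$data, g$spacing, g2$origin, R)
  ax2 <- structure(list(ml_axis = as.numeric(R %*% ax$ml_axis),
                        ap_axis = as.numeric(R %*% ax$ap_axis),
                        plane_normal = as.numeric(R %*% ax$plane_normal)),
                   class = "meniscus_axes")
  u2 <- u %*% t(R)
  sm2 <- segment_motion(deformation_field(u2, g2), labs2, ax2, "MM")
  expect_equal(sm2$avg_mm, sm$avg_mm, tolerance = 1e-8)
  expect_equal(sm2$ml_mm, sm$ml_mm, tolerance = 1e-8)
  expect_equal(sm2$ap_mm, sm$ap_mm, tolerance = 1e-8)
})
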