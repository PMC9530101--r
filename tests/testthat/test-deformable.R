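make_translation_pair <- function(d = c(48, 48, 16), shift = c(2, 1, 0)) {
  g <- centred_grid(d)
  tm <- crescent_mask(g)
  mm <- crescent_mask(g, shift = shift)
  list(grid = g, template = tm, moving = mm, shift = shift)
}

test_that("ssd_term evaluates its definition", {
  # identical images, zero field
  g <- centred_grid(c(8, 8, 8))
  img <- knee_volume(array(rnorm(512), c(8, 8, 8)), g$spacing, g$origin)
  zero <- deformation_field(matrix(0, 512, 3), g)
  expect_equal(ssd_term(img, img, zero), 0)

  # one-voxel domain, values 1 and 3, voxel volume 1: 1/2 * 2^2 = 2
  g1 <- knee_volume(array(1, c(1, 1, 1)), c(1, 1, 1))
  a <- knee_volume(array(1, c(1, 1, 1)))
  b <- knee_volume(array(3, c(1, 1, 1)))
  z1 <- deformation_field(matrix(0, 1, 3), g1)
  expect_equal(ssd_term(a, b, z1), 2.0)

  # moving = template shifted by a known field: SSD at u* is at the
  # interpolation floor relative to u = 0
  d <- c(20, 20, 12)
  g2 <- centred_grid(d)
  X <- grid_world_coords(g2)
  tpl <- knee_volume(array(exp(-rowSums(X^2) / 12), d), g2$spacing, g2$origin)
  mv <- knee_volume(array(exp(-rowSums(sweep(X, 2, c(-2, 0, 0), "+")^2) / 12),
                          d), g2$spacing, g2$origin)  # shifted by +2 in x
  ustar <- deformation_field(matrix(rep(c(2, 0, 0), each = prod(d)),
                                    ncol = 3), g2)
  zero2 <- deformation_field(matrix(0, prod(d), 3), g2)
  expect_lt(ssd_term(tpl, mv, ustar), 1e-3 * ssd_term(tpl, mv, zero2))
})

test_that("curvature_term vanishes on affine fields and matches the
           closed form for a sinusoidal field", {
  n <- 64; h <- 10 / n
  g <- knee_volume(array(0, c(n, n, n)), c(h, h, h))
  X <- grid_world_coords(g)

  zero <- deformation_field(matrix(0, n^3, 3), g)
  expect_equal(curvature_term(zero), 0)

  A <- matrix(c(0.3, -0.2, 0.1, 0.05, 0.2, -0.15, 0.02, 0.07, -0.3), 3)
  aff <- sweep(X %*% t(A), 2, c(1, -2, 0.5), "+")
  expect_lt(curvature_term(deformation_field(aff, g)),
            1e-10 * max(1, sum(aff^2)))

  # u1 = sin(pi x / 10) on a 10 mm cube: S[u] = 1/2 (pi/10)^4 * 5 * 100
  # = pi^4 / 40 (quadrature oracle: integral sin^2 over [0,10] is 5)
  quad_x <- seq(0, 10, length.out = 2001)
  oracle <- 0.5 * (pi / 10)^4 * trapz_int(quad_x, sin(pi * quad_x / 10)^2) * 100
  expect_equal(oracle, pi^4 / 40, tolerance = 1e-6)
  u <- cbind(sin(pi * X[, 1] / 10), 0, 0)
  val <- curvature_term(deformation_field(u, g))
  expect_lt(abs(val - oracle) / oracle, 0.05)
})

test_that("distance_term evaluates its definition", {
  d <- c(12, 10, 8)
  g <- centred_grid(d)
  m <- array(0, d); m[4, 5, 4] <- 1
  tpl_mask <- label_mask(m, g$spacing, g$origin)
  zero <- deformation_field(matrix(0, prod(d), 3), g)

  # identical masks, zero field: distance map is 0 on the foreground
  expect_equal(distance_term(zero, tpl_mask,
                             euclidean_distance_map(tpl_mask)), 0)

  # masks offset by 3 voxels along an axis (1 mm spacing): 1/2 * 3^2
  m2 <- array(0, d); m2[7, 5, 4] <- 1
  mov_mask <- label_mask(m2, g$spacing, g$origin)
  dmov <- euclidean_distance_map(mov_mask)
  expect_equal(distance_term(zero, tpl_mask, dmov), 4.5)

  # the field that carries the template voxel's content onto the moving
  # voxel (the true motion) zeroes the penalty
  u <- matrix(rep(c(3, 0, 0), each = prod(d)), ncol = 3)
  expect_equal(distance_term(deformation_field(u, g), tpl_mask, dmov), 0)
  expect_error(distance_term(zero, label_mask(array(0, d), g$spacing,
                                              g$origin), dmov), "empty")
})

test_that("registering a mask to itself yields a negligible field", {
  p <- make_translation_pair(shift = c(0, 0, 0))
  fld <- register_deformable(p$template, p$moving)
  expect_lt(max(sqrt(rowSums(fld$u^2))), 0.1 * min(p$grid$spacing))
})

test_that("a 2 mm in-plane translation is recovered with a monotone
           objective and a useful prolongation", {
  p <- make_translation_pair(shift = c(2, 1, 0))
  fld <- register_deformable(p$template, p$moving)
  idx <- which(p$template$data > 0.5)
  err <- sqrt(rowSums(sweep(fld$u[idx, ], 2, c(2, 1, 0), "-")^2))
  expect_lt(mean(err), 0.5)

  # accepted Gauss-Newton iterates never increase the objective
  tr <- attr(fld, "trace")
  for (lv in unique(tr$level))
    expect_true(all(diff(tr$total[tr$level == lv]) <= 1e-9))

  # the prolonged coarse solution must not leave the fine level worse (by
  # more than 5%) than an uninitialised fine level would be
  w <- objective_weights()
  zero <- deformation_field(matrix(0, prod(dim(p$template$data)), 3),
                            p$template)
  J0 <- ssd_term(smooth_volume(p$template, 1), smooth_volume(p$moving, 1),
                 zero) +
    w$alpha * curvature_term(zero) +
    w$beta * distance_term(zero, p$template,
                           euclidean_distance_map(p$moving))
  fine_start <- tr$total[tr$level == 1 & tr$iter == 0]
  expect_lt(fine_start, 1.05 * J0)
})

test_that("objective decomposes exactly into its three terms", {
  p <- make_translation_pair(shift = c(2, 1, 0))
  sched <- multilevel_schedule(n_levels = 1, max_iter_per_level = 3)
  w <- objective_weights(alpha = 1, beta = 0.1)
  fld <- register_deformable(p$template, p$moving, w, sched)
  tr <- attr(fld, "trace")
  last <- tr[nrow(tr), ]
  # recompute the terms independently from the returned field
  sig <- sched$smoothing_sigma
  Timg <- smooth_volume(p$template, sig)
  Mimg <- smooth_volume(p$moving, sig)
  dmap <- euclidean_distance_map(p$moving)
  s <- ssd_term(Timg, Mimg, fld)
  cv <- curvature_term(fld)
  dt <- distance_term(fld, p$template, dmap)
  expect_equal(s, last$ssd, tolerance = 1e-10)
  expect_equal(cv, last$curvature, tolerance = 1e-10)
  expect_equal(dt, last$distance, tolerance = 1e-10)
  expect_equal(s + w$alpha * cv + w$beta * dt, last$total, tolerance = 1e-10)
})



test_that("empty masks are rejected", {
  g <- centred_grid(c(16, 16, 16))
  empty <- label_mask(array(0, c(16, 16, 16)), g$spacing, g$origin)
  full <- crescent_mask(g, r_in = 3, r_out = 6, zh = 3)
  expect_error(register_deformable(empty, full), "empty")
  expect_error(register_deformable(full, empty), "empty")
})

test_that("with beta = 0 non-overlapping masks give the SSD no usable
           signal, with beta > 0 overlap is achieved", {
  d <- c(48, 48, 32)
  g <- centred_grid(d)
  # crescent pieces separated by a 6 mm gap, zero overlap
  tm <- crescent_mask(g, r_in = 4, r_out = 9, span_deg = 120, zh = 2,
                      center = c(0, 0))
  mm <- crescent_mask(g, r_in = 4, r_out = 9, span_deg = 120, zh = 2,
                      center = c(0, 0), shift = c(0, -13, 0))
  expect_equal(sum(tm$data * mm$data), 0)  # truly disjoint

  # beta = 0: separated smoothed indicators give the SSD no signal to
  # close the gap — only sub-voxel boundary jitter, no capture
  f0 <- register_deformable(tm, mm, objective_weights(alpha = 1, beta = 0),
                            multilevel_schedule(n_levels = 1,
                                                max_iter_per_level = 10))
  expect_lt(mean(sqrt(rowSums(f0$u^2))), 0.5)
  expect_equal(dice_coef(tm, resample(mm, f0, "nearest")), 0)

  f1 <- register_deformable(tm, mm, objective_weights(alpha = 1, beta = 0.1),
                            multilevel_schedule(max_iter_per_level = 150))
  warped <- resample(mm, f1, "nearest")
  expect_gt(dice_coef(tm, warped), 0.8)
})

test_that("the solver is deterministic", {
  p <- make_translation_pair(d = c(24, 24, 12), shift = c(1.5, 0.5, 0))
  f1 <- register_deformable(p$template, p$moving, seed = 1)
  f2 <- register_deformable(p$template, p$moving, seed = 99)
  expect_identical(f1$u, f2$u)
})
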