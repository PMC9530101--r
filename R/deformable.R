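#' Objective weights for deformable registration
#'
#' The nonlinear stage minimises
#' `J[u] = SSD(T, M, u) + alpha * curvature(u) + beta * distance(u)`,
#' where the data images are Gaussian-smoothed meniscus-mask indicators,
#' `curvature` penalises the squared Laplacian of each displacement
#' component and `distance` scores, point-wise, the distance between the
#' warped template-meniscus voxels and the moving meniscus via its distance
#' map (the term that provides capture range when the masks do not
#' initially overlap).
#'
#' @param alpha Curvature-regularizer weight (> 0, mm-scale of the
#'   Laplacian energy).
#' @param beta Distance-penalty weight (>= 0, applied to squared mm).
#' @export
objective_weights <- function(alpha = 1.0, beta = 0.1) {
  alpha <- as.numeric(alpha); beta <- as.numeric(beta)
  if (!is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be > 0 (the regularized problem must be well-posed)")
  if (!is.finite(beta) || beta < 0) stop("`beta` must be >= 0")
  structure(list(alpha = alpha, beta = beta), class = "objective_weights")
}

#' Multilevel schedule for the Gauss-Newton solver
#'
#' @param n_levels Number of resolution levels (factor-2 pyramid); clamped
#'   so the coarsest grid keeps at least 8 voxels per axis.
#' @param downsample_factor Per-level downsampling factor (only 2 is
#'   supported).
#' @param max_iter_per_level Outer Gauss-Newton iteration cap per level.
#' @param tol_rel Relative objective-decrease stopping tolerance.
#' @param smoothing_sigma Gaussian sigma (in voxels of each level) applied
#'   to the mask indicator images that drive the SSD term.
#' @param cg_max_iter,cg_tol Inner conjugate-gradient cap and relative
#'   residual tolerance for the matrix-free normal equations.
#' @export
multilevel_schedule <- function(n_levels = 3, downsample_factor = 2,
                                max_iter_per_level = 50, tol_rel = 1e-4,
                                smoothing_sigma = 1,
                                cg_max_iter = 30, cg_tol = 1e-2) {
  if (n_levels < 1) stop("`n_levels` must be >= 1")
  if (downsample_factor != 2) stop("only factor-2 downsampling is supported")
  structure(list(n_levels = as.integer(n_levels),
                 downsample_factor = 2L,
                 max_iter_per_level = as.integer(max_iter_per_level),
                 tol_rel = tol_rel, smoothing_sigma = smoothing_sigma,
                 cg_max_iter = as.integer(cg_max_iter), cg_tol = cg_tol),
            class = "multilevel_schedule")
}

# fractional voxel coordinates of every grid point displaced by u (mm, world)
warp_voxel_coords <- function(index_mat, u, spacing, orientation) {
  index_mat + sweep(u %*% orientation, 2, spacing, "/")
}

#' Sum-of-squared-differences data term
#'
#' `1/2 * sum_x (T(x) - M(x + u(x)))^2 * voxel volume`, with trilinear
#' sampling of the moving image at the displaced voxel centres.
#'
#' @param template_img,moving_img `knee_volume`s on the same grid.
#' @param u A `deformation_field` on that grid.
#' @return Scalar (intensity^2 x mm^3).
#' @export
ssd_term <- function(template_img, moving_img, u) {
  stop_if_grid_mismatch(template_img, moving_img, "template and moving images")
  stop_if_grid_mismatch(template_img, field_geometry(u), "images and field")
  d <- dim(template_img$data)
  vox <- warp_voxel_coords(grid_index_matrix(d), field_matrix(u),
                           template_img$spacing, template_img$orientation)
  Mw <- sample_trilinear_cpp(as.numeric(moving_img$data), d, vox, 0)
  0.5 * voxel_volume(template_img) * sum((as.numeric(template_img$data) - Mw)^2)
}

#' Curvature regularisation term
#'
#' Discretisation of `1/2 * sum_l integral (Laplacian u_l)^2 dx` with
#' spacing-aware second-order central differences.  At the grid boundary
#' the field is extended linearly (free boundary), so any affine field has
#' exactly zero curvature energy.
#'
#' @param u A `deformation_field`.
#' @return Scalar (mm^3 x mm^-2).
#' @export
curvature_term <- function(u) {
  U <- field_matrix(u)
  if (any(!is.finite(U))) stop("non-finite deformation field")
  g <- u$geometry
  vv <- prod(g$spacing)
  acc <- 0
  for (cmp in 1:3) {
    L <- laplacian_cpp(U[, cmp], g$dim, g$spacing)
    acc <- acc + sum(L^2)
  }
  0.5 * vv * acc
}

#' Distance-transform shape penalty
#'
#' `1/2 * sum_{x in template meniscus} D_mov(x + u(x))^2 * voxel volume`:
#' for every template-meniscus voxel, the Euclidean distance (trilinearly
#' sampled from the moving meniscus' precomputed distance map) between its
#' warped position and the moving meniscus, squared.  The term measures
#' point-wise the distance between the two meniscus faces under the current
#' field; it vanishes exactly when every template-meniscus voxel warps onto
#' the moving meniscus, and — unlike the SSD term — its gradient
#' (`D * grad D`, with `|grad D| = 1`) is defined at any separation, which
#' is what gives the registration capture range when the masks share no
#' initial overlap.
#'
#' @param u A `deformation_field`.
#' @param template_meniscus Non-empty `label_mask` on the template grid;
#'   the fixed support of the sum.
#' @param moving_distance_map Output of [euclidean_distance_map()] for the
#'   moving meniscus mask.
#' @return Scalar (mm^2 x mm^3).
#' @export
distance_term <- function(u, template_meniscus, moving_distance_map) {
  idx <- which(template_meniscus$data > 0.5)
  if (!length(idx)) stop("template meniscus mask is empty")
  stop_if_grid_mismatch(template_meniscus, moving_distance_map,
                        "mask and distance map")
  g <- u$geometry
  d <- g$dim
  I0 <- grid_index_matrix(d)[idx, , drop = FALSE]
  vox <- warp_voxel_coords(I0, field_matrix(u)[idx, , drop = FALSE],
                           g$spacing, g$orientation)
  Dw <- sample_trilinear_cpp(as.numeric(moving_distance_map$data), d, vox,
                             max(moving_distance_map$data))
  0.5 * prod(g$spacing) * sum(Dw^2)
}

#' Deformable registration of meniscus masks
#'
#' Estimates a dense displacement field `u` (mm, template grid) minimising
#' `J[u] = SSD + alpha * curvature + beta * distance` over the smoothed
#' indicator images of the two masks, using a matrix-free Gauss-Newton
#' method: at each outer iteration the Gauss-Newton normal equations are
#' solved approximately by conjugate gradients using only operator-vector
#' products, followed by an Armijo backtracking line search, embedded in a
#' coarse-to-fine multilevel scheme.  Accepted steps never increase the
#' objective.  The solver is fully deterministic; `seed` is accepted only
#' for interface uniformity.
#'
#' @param template_mask,moving_mask Non-empty `label_mask`s on a shared
#'   grid (already rigidly aligned to the tibia frame).
#' @param weights An [objective_weights()].
#' @param schedule A [multilevel_schedule()].
#' @param seed Ignored (no stochastic steps).
#' @param init Optional initial field: a `deformation_field` on the same
#'   grid or an n x 3 matrix (mm).  See [init_field_from_centroids()] for a
#'   mask-based translation pre-alignment.
#' @param verbose Print per-iteration objective values.
#' @return A `deformation_field` with attributes `trace` (data.frame with
#'   level, iter, ssd, curvature, distance, total) and `converged`.
#' @export
register_deformable <- function(template_mask, moving_mask,
                                weights = objective_weights(),
                                schedule = multilevel_schedule(),
                                seed = NULL, init = NULL, verbose = FALSE) {
  stop_if_grid_mismatch(template_mask, moving_mask, "template and moving masks")
  if (sum(template_mask$data > 0.5) == 0L) stop("template mask is empty")
  if (sum(moving_mask$data > 0.5) == 0L) stop("moving mask is empty")

  # resolution pyramid of binary masks, finest first
  lv_t <- list(template_mask); lv_m <- list(moving_mask)
  n_levels <- schedule$n_levels
  for (l in seq_len(n_levels - 1)) {
    nt <- as_label_mask(downsample2(lv_t[[l]]))
    if (any(dim(nt$data) < 8) || sum(nt$data) == 0) { n_levels <- l; break }
    nm <- as_label_mask(downsample2(lv_m[[l]]))
    if (sum(nm$data) == 0) { n_levels <- l; break }
    lv_t[[l + 1]] <- nt; lv_m[[l + 1]] <- nm
  }

  u <- NULL
  trace <- list()
  prev_level_J <- NA_real_
  for (l in rev(seq_len(n_levels))) {
    tm <- lv_t[[l]]; mm <- lv_m[[l]]
    d <- dim(tm$data)
    sig <- schedule$smoothing_sigma
    Timg <- smooth_volume(tm, sig)$data
    Mimg <- smooth_volume(mm, sig)$data
    Dmap <- euclidean_distance_map(mm)$data
    I0 <- grid_index_matrix(d)
    midx <- which(tm$data > 0.5)
    if (is.null(u)) {
      if (is.null(init)) {
        u <- matrix(0, prod(d), 3)
      } else {
        # restrict / resample the initial field onto the coarsest level
        u0 <- if (inherits(init, "deformation_field")) init
              else deformation_field(init, template_mask)
        stop_if_grid_mismatch(field_geometry(u0), template_mask,
                              "init field and template mask")
        u <- sample_field(u0, grid_world_coords(tm))
      }
    } else {
      # prolongation: coarse voxel coordinate of fine voxel i is i/2;
      # smooth afterwards because piecewise-trilinear upsampling carries
      # slope kinks that the fine-level curvature term would punish
      uf <- matrix(0, prod(d), 3)
      dc <- dim(lv_t[[l + 1]]$data)
      for (cmp in 1:3) {
        up <- sample_trilinear_cpp(u[, cmp], dc, I0 / 2, 0)
        uf[, cmp] <- gaussian_smooth_cpp(up, d, c(1, 1, 1))
      }
      u <- uf
    }
    sol <- gn_solve_level(u, Timg, Mimg, Dmap, midx, I0, d,
                          tm$spacing, tm$orientation, weights, schedule,
                          level = l, verbose = verbose,
                          J_prev_level = prev_level_J)
    u <- sol$u
    trace[[length(trace) + 1]] <- sol$trace
    prev_level_J <- sol$final_J
  }
  trace <- do.call(rbind, trace)
  out <- deformation_field(u, template_mask)
  attr(out, "trace") <- trace
  attr(out, "converged") <- TRUE
  out
}

# Gauss-Newton with CG inner solves and Armijo line search on one level.
# midx: template-mask voxel indices (fixed support of the distance term);
# Dmap: Euclidean distance map of the moving mask (mm).
gn_solve_level <- function(u, Timg, Mimg, Dmap, midx, I0, d, spacing,
                           orientation, weights, schedule, level,
                           verbose = FALSE, J_prev_level = NA_real_) {
  vv <- prod(spacing)
  alpha <- weights$alpha; beta <- weights$beta
  Tv <- as.numeric(Timg); Mv <- as.numeric(Mimg)
  Dv <- as.numeric(Dmap)
  Dfill <- max(Dv)  # leaving the domain must not be rewarded
  n <- nrow(u)
  ridge <- 1e-8 * vv

  terms <- function(u) {
    vox <- warp_voxel_coords(I0, u, spacing, orientation)
    Mw <- sample_trilinear_cpp(Mv, d, vox, 0)
    ssd <- 0.5 * vv * sum((Tv - Mw)^2)
    curv <- 0
    for (cmp in 1:3) curv <- curv + sum(laplacian_cpp(u[, cmp], d, spacing)^2)
    curv <- 0.5 * vv * curv
    dist <- 0
    if (beta > 0 && length(midx)) {
      Dw <- sample_trilinear_cpp(Dv, d, vox[midx, , drop = FALSE], Dfill)
      dist <- 0.5 * vv * sum(Dw^2)
    }
    c(ssd = ssd, curvature = curv, distance = dist,
      total = ssd + alpha * curv + beta * dist)
  }

  tr <- list()
  Jt <- terms(u)
  if (!all(is.finite(Jt))) stop("non-finite objective: solver diverged")
  tr[[1]] <- data.frame(level = level, iter = 0L, ssd = Jt[["ssd"]],
                        curvature = Jt[["curvature"]],
                        distance = Jt[["distance"]], total = Jt[["total"]])
  J <- Jt[["total"]]

  for (it in seq_len(schedule$max_iter_per_level)) {
    vox <- warp_voxel_coords(I0, u, spacing, orientation)
    sg <- sample_trilinear_grad_cpp(Mv, d, vox, 0)
    Mw <- sg[, 1]
    Gw <- sweep(sg[, 2:4, drop = FALSE], 2, spacing, "/") %*% t(orientation)
    r <- Mw - Tv

    Lu <- vapply(1:3, function(cmp) laplacian_cpp(u[, cmp], d, spacing),
                 numeric(n))

    g <- vv * Gw * r
    for (cmp in 1:3)
      g[, cmp] <- g[, cmp] +
        alpha * vv * laplacian_adjoint_cpp(Lu[, cmp], d, spacing)

    use_dist <- beta > 0 && length(midx) > 0
    if (use_dist) {
      # residual D_mov(x + u) on the template mask: gradient D * grad D,
      # Gauss-Newton Jacobian grad D
      sgd <- sample_trilinear_grad_cpp(Dv, d, vox[midx, , drop = FALSE],
                                       Dfill)
      Dw <- sgd[, 1]
      Jd <- sweep(sgd[, 2:4, drop = FALSE], 2, spacing, "/") %*%
        t(orientation)
      didx <- midx
      g[didx, ] <- g[didx, ] + beta * vv * Jd * Dw
    }

    gnorm <- sqrt(sum(g^2))
    if (gnorm < 1e-12) break

    if (!use_dist) { didx <- integer(0); Jd <- matrix(0, 0, 3) }
    Hp <- function(p) gn_hessian_apply_cpp(p, Gw, d, spacing, alpha, vv,
                                           ridge, didx, Jd, beta)

    # Jacobi preconditioner: diagonal of the Gauss-Newton Hessian
    w2 <- 1 / spacing^2
    dcurv <- (2 * sum(w2))^2 + 2 * sum(w2^2)
    Mdiag <- vv * Gw^2 + alpha * vv * dcurv + ridge
    if (use_dist)
      Mdiag[didx, ] <- Mdiag[didx, ] + beta * vv * Jd^2
    delta <- cg_solve(Hp, -g, schedule$cg_max_iter, schedule$cg_tol,
                      precond = Mdiag)
    m <- sum(g * delta)
    if (!is.finite(m) || m >= 0) { delta <- -g; m <- -gnorm^2 }

    # Armijo backtracking (factor 0.5, c = 1e-4)
    step <- 1; accepted <- FALSE
    for (ls in 1:20) {
      u_try <- u + step * delta
      Jt_try <- terms(u_try)
      if (!all(is.finite(Jt_try))) stop("non-finite objective: solver diverged")
      if (Jt_try[["total"]] <= J + 1e-4 * step * m) {
        u <- u_try; Jt <- Jt_try; accepted <- TRUE; break
      }
      step <- step / 2
    }
    if (!accepted) break
    J_new <- Jt[["total"]]
    tr[[length(tr) + 1]] <- data.frame(level = level, iter = it,
                                       ssd = Jt[["ssd"]],
                                       curvature = Jt[["curvature"]],
                                       distance = Jt[["distance"]],
                                       total = J_new)
    if (verbose)
      message(sprintf("level %d iter %d: J = %.6g (ssd %.4g curv %.4g dist %.4g)",
                      level, it, J_new, Jt[["ssd"]], Jt[["curvature"]],
                      Jt[["distance"]]))
    if ((J - J_new) / max(J, .Machine$double.eps) < schedule$tol_rel) {
      J <- J_new; break
    }
    J <- J_new
  }
  list(u = u, trace = do.call(rbind, tr), final_J = J)
}

#' Translation pre-alignment field from mask centroids
#'
#' Builds a smooth initial displacement field for [register_deformable()]
#' from the centroid shift of each meniscus mask pair (template vs rigidly
#' aligned moving), applied through Gaussian windows of the template-mask
#' distance maps so each meniscus carries its own translation and the field
#' decays smoothly in between.  A standard block-initialisation that gives
#' the Gauss-Newton solve a head start when meniscal displacements span
#' several voxels.
#'
#' @param pairs List of `list(template = mask, moving = mask)` pairs on a
#'   common grid (one entry per meniscus).
#' @param sigma Window decay in mm.
#' @return A `deformation_field` on the masks' grid.
#' @export
init_field_from_centroids <- function(pairs, sigma = 8) {
  g <- pairs[[1]]$template
  u <- matrix(0, prod(dim(g$data)), 3)
  for (pr in pairs) {
    stop_if_grid_mismatch(pr$template, g, "mask pairs")
    ct <- colMeans(mask_world_coords(pr$template))
    cm <- colMeans(mask_world_coords(pr$moving))
    dmap <- as.numeric(euclidean_distance_map(pr$template)$data)
    w <- exp(-dmap^2 / (2 * sigma^2))
    u <- u + outer(w, cm - ct)
  }
  deformation_field(u, g)
}

#' Affine pre-alignment field from mask moments
#'
#' Like [init_field_from_centroids()], but each mask pair contributes a
#' full affine map matched from its first and second voxel moments
#' (centroids plus principal-axis scalings: `L = R_m S_m (R_t S_t)^-1`
#' with sign-aligned eigenvectors), so a deformation's bulk linear part is
#' in the initial field as well.  If the fitted linear part deviates
#' strongly from the identity (operator deviation above `max_linear`), it
#' is discarded in favour of the pure translation — near-symmetric masks
#' make the rotation ill-determined.
#'
#' @inheritParams init_field_from_centroids
#' @param max_linear Cap on `max |L - I|` before falling back to
#'   translation.
#' @export
init_field_from_moments <- function(pairs, sigma = 8, max_linear = 0.3) {
  g <- pairs[[1]]$template
  u <- matrix(0, prod(dim(g$data)), 3)
  X <- grid_world_coords(g)
  for (pr in pairs) {
    stop_if_grid_mismatch(pr$template, g, "mask pairs")
    Xt <- mask_world_coords(pr$template)
    Xm <- mask_world_coords(pr$moving)
    ct <- colMeans(Xt); cm <- colMeans(Xm)
    et <- eigen(stats::cov(Xt), symmetric = TRUE)
    em <- eigen(stats::cov(Xm), symmetric = TRUE)
    # align eigenvector signs so the two frames agree
    for (k in 1:3)
      if (sum(em$vectors[, k] * et$vectors[, k]) < 0)
        em$vectors[, k] <- -em$vectors[, k]
    L <- em$vectors %*% diag(sqrt(pmax(em$values, 1e-12))) %*%
      diag(1 / sqrt(pmax(et$values, 1e-12))) %*% t(et$vectors)
    if (max(abs(L - diag(3))) > max_linear) L <- diag(3)
    dmap <- as.numeric(euclidean_distance_map(pr$template)$data)
    w <- exp(-dmap^2 / (2 * sigma^2))
    disp <- sweep(sweep(X, 2, ct, "-") %*% t(L), 2, cm, "+") - X
    u <- u + disp * w
  }
  deformation_field(u, g)
}

# matrix-free preconditioned conjugate gradients for H delta = b
cg_solve <- function(Hp, b, max_iter, tol, precond = NULL) {
  x <- b * 0
  r <- b
  b0 <- sqrt(sum(r * r))
  if (b0 == 0) return(x)
  z <- if (is.null(precond)) r else r / precond
  p <- z
  rz <- sum(r * z)
  for (i in seq_len(max_iter)) {
    Ap <- Hp(p)
    pAp <- sum(p * Ap)
    if (pAp <= 0) break
    a <- rz / pAp
    x <- x + a * p
    r <- r - a * Ap
    if (sqrt(sum(r * r)) <= tol * b0) break
    z <- if (is.null(precond)) r else r / precond
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  x
}
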