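#' Rigid transform (6 degrees of freedom)
#'
#' A rotation (Euler angles, radians, applied as `Rz %*% Ry %*% Rx`) about a
#' fixed centre plus a translation, mapping template-frame world coordinates
#' into the moving frame: `phi(x) = R (x - c) + c + t`.
#'
#' @param angles Length-3 rotation angles (radians) about x, y, z.
#' @param translation Length-3 translation (mm).
#' @param center Length-3 rotation centre (mm, world).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  angles <- as.numeric(angles); translation <- as.numeric(translation)
  center <- as.numeric(center)
  stopifnot(length(angles) == 3L, length(translation) == 3L,
            length(center) == 3L)
  if (any(!is.finite(c(angles, translation, center))))
    stop("rigid transform parameters must be finite")
  structure(list(angles = angles, translation = translation, center = center),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (deg): %s | trans (mm): %s | centre: %s\n",
              paste(signif(x$angles * 180 / pi, 4), collapse = ", "),
              paste(signif(x$translation, 4), collapse = ", "),
              paste(signif(x$center, 4), collapse = ", ")))
  invisible(x)
}

euler_to_matrix <- function(angles) {
  ca <- cos(angles[1]); sa <- sin(angles[1])
  cb <- cos(angles[2]); sb <- sin(angles[2])
  cc <- cos(angles[3]); sc <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca))
  Ry <- rbind(c(cb, 0, sb), c(0, 1, 0), c(-sb, 0, cb))
  Rz <- rbind(c(cc, -sc, 0), c(sc, cc, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

matrix_to_euler <- function(R) {
  # inverse of Rz(g) Ry(b) Rx(a); valid away from |b| = pi/2
  b <- asin(max(-1, min(1, -R[3, 1])))
  a <- atan2(R[3, 2], R[3, 3])
  g <- atan2(R[2, 1], R[1, 1])
  c(a, b, g)
}

#' 4x4 homogeneous matrix of a rigid transform
#' @param transform A `rigid_transform`.
#' @export
rigid_matrix <- function(transform) {
  R <- euler_to_matrix(transform$angles)
  A <- diag(4)
  A[1:3, 1:3] <- R
  A[1:3, 4] <- transform$center - R %*% transform$center + transform$translation
  A
}

#' Invert a rigid transform
#' @param transform A `rigid_transform`.
#' @export
rigid_invert <- function(transform) {
  R <- euler_to_matrix(transform$angles)
  rigid_transform(angles = matrix_to_euler(t(R)),
                  translation = as.numeric(-t(R) %*% transform$translation),
                  center = transform$center)
}

#' Compose two rigid transforms (`a` after `b`)
#'
#' Returns the transform equivalent to applying `b` first and `a` second,
#' expressed about the centre of `a`.
#' @param a,b `rigid_transform` objects.
#' @export
rigid_compose <- function(a, b) {
  M <- rigid_matrix(a) %*% rigid_matrix(b)
  R <- M[1:3, 1:3]
  c0 <- a$center
  rigid_transform(angles = matrix_to_euler(R),
                  translation = as.numeric(M[1:3, 4] - c0 + R %*% c0),
                  center = c0)
}

#' Apply a rigid transform to world points
#' @param transform A `rigid_transform`.
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @export
rigid_apply <- function(transform, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  R <- euler_to_matrix(transform$angles)
  sweep(sweep(xyz, 2, transform$center, "-") %*% t(R), 2,
        transform$center + transform$translation, "+")
}

#' Resample a volume through a transform onto a template grid
#'
#' For every voxel centre `x` of the target grid the moving volume is
#' sampled at `phi(x)` (rigid) or `x + u(x)` (dense displacement field).
#' Samples outside the moving domain are filled with 0.  Nearest-neighbour
#' interpolation is required for label masks.
#'
#' @param vol Moving `knee_volume` (or `label_mask`).
#' @param transform A `rigid_transform` or `deformation_field`; `NULL` means
#'   identity.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param grid Target-grid `knee_volume`; defaults to the field's grid for
#'   dense fields, else to `vol`'s own grid.
#' @return Resampled volume on the target grid.
#' @export
resample <- function(vol, transform = NULL,
                     interpolation = c("trilinear", "nearest"), grid = NULL) {
  interpolation <- match.arg(interpolation)
  if (inherits(vol, "label_mask") && interpolation != "nearest")
    stop("label masks must be resampled with nearest-neighbour interpolation")
  if (inherits(transform, "deformation_field")) {
    fgrid <- field_geometry(transform)
    if (!is.null(grid)) stop_if_grid_mismatch(fgrid, grid, "field and grid")
    grid <- fgrid
  }
  if (is.null(grid)) grid <- vol
  X <- grid_world_coords(grid)
  if (is.null(transform)) {
    Y <- X
  } else if (inherits(transform, "rigid_transform")) {
    Y <- rigid_apply(transform, X)
  } else if (inherits(transform, "deformation_field")) {
    Y <- X + field_matrix(transform)
  } else stop("unsupported transform of class ", class(transform)[1])
  vox <- world_to_voxel(vol, Y)
  vals <- if (interpolation == "trilinear")
    sample_trilinear_cpp(as.numeric(vol$data), dim(vol$data), vox, 0)
  else
    sample_nearest_cpp(as.numeric(vol$data), dim(vol$data), vox, 0)
  out <- array(vals, dim(grid$data))
  if (inherits(vol, "label_mask"))
    label_mask(out, grid$spacing, grid$origin, grid$orientation,
               label_name = vol$label_name)
  else
    knee_volume(out, grid$spacing, grid$origin, grid$orientation)
}

#' Rigid registration of a moving volume to a template, anchored on a mask
#'
#' Estimates the 6-DOF transform minimising the sum-of-squared-differences
#' restricted to the template tibia mask,
#' `sum_x (T(x) - M(phi(x)))^2 * voxel volume`, by multilevel BFGS with
#' analytic gradients.  The rotation centre is the tibia-mask centroid.
#'
#' @param template Template `knee_volume`.
#' @param moving Moving `knee_volume` (same subject, other position).
#' @param tibia_mask Non-empty `label_mask` on the template grid.
#' @param levels Number of resolution levels (factor-2 pyramid).
#' @param max_iter BFGS iteration cap per level.
#' @param smooth_sigma Gaussian smoothing (voxels) applied to both images
#'   at the finest level; damps the sub-voxel bias that interpolating
#'   image noise otherwise imprints on the SSD minimum.
#' @param init Optional initial `rigid_transform`.
#' @return A `rigid_transform` with attribute `objective` =
#'   `c(identity, solution)`.
#' @export
register_rigid <- function(template, moving, tibia_mask,
                           levels = 3, max_iter = 100, smooth_sigma = 1,
                           init = NULL) {
  stop_if_grid_mismatch(template, tibia_mask, "template and tibia mask")
  if (sum(tibia_mask$data > 0.5) == 0L) stop("tibia mask is empty")
  if (any(!is.finite(template$data)) || any(!is.finite(moving$data)))
    stop("non-finite image values")

  idx <- which(tibia_mask$data > 0.5)
  X0 <- voxel_to_world(template, grid_index_matrix(dim(template$data))[idx, , drop = FALSE])
  center <- colMeans(X0)
  p <- if (is.null(init)) rep(0, 6)
       else c(init$angles, init$translation)

  # pyramid, coarse to fine
  if (smooth_sigma > 0) {
    template <- smooth_volume(template, smooth_sigma)
    moving <- smooth_volume(moving, smooth_sigma)
  }
  pyr <- list(list(t = template, m = moving, mask = tibia_mask))
  for (l in seq_len(levels - 1)) {
    prev <- pyr[[1]]
    pyr <- c(list(list(t = downsample2(prev$t), m = downsample2(prev$m),
                       mask = as_label_mask(downsample2(prev$mask)))), pyr)
  }

  obj_identity <- NA_real_
  for (l in seq_along(pyr)) {
    lv <- pyr[[l]]
    midx <- which(lv$mask$data > 0.5)
    if (!length(midx)) next
    Xl <- voxel_to_world(lv$t, grid_index_matrix(dim(lv$t$data))[midx, , drop = FALSE])
    Tv <- as.numeric(lv$t$data)[midx]
    vv <- voxel_volume(lv$t)
    mdat <- as.numeric(lv$m$data); mdim <- dim(lv$m$data)
    sp <- lv$m$spacing; orr <- lv$m$orientation

    # Samples whose warped position leaves the moving FOV carry zero-fill
    # values and would bias the masked SSD.  The inclusion set is frozen
    # at the current estimate for each optimisation pass (a set that moves
    # with the parameters can be gamed by pushing high-residual edge
    # samples out of the FOV) and the fit is repeated with the set
    # recomputed at the new estimate.
    inside_at <- function(p, buffer = 3) {
      tr <- rigid_transform(p[1:3], p[4:6], center)
      vox <- world_to_voxel(lv$m, rigid_apply(tr, Xl))
      vox[, 1] >= buffer & vox[, 1] <= mdim[1] - 1 - buffer &
        vox[, 2] >= buffer & vox[, 2] <= mdim[2] - 1 - buffer &
        vox[, 3] >= buffer & vox[, 3] <= mdim[3] - 1 - buffer
    }
    make_obj <- function(keep) {
      Tk <- Tv[keep]
      Xk <- Xl[keep, , drop = FALSE]
      Xck <- sweep(Xk, 2, center, "-")
      fn <- function(p) {
        tr <- rigid_transform(p[1:3], p[4:6], center)
        vox <- world_to_voxel(lv$m, rigid_apply(tr, Xk))
        Mv <- sample_trilinear_cpp(mdat, mdim, vox, 0)
        sum((Tk - Mv)^2) * vv
      }
      gr <- function(p) {
        R <- euler_to_matrix(p[1:3])
        Y <- sweep(Xck %*% t(R), 2, center + p[4:6], "+")
        vox <- world_to_voxel(lv$m, Y)
        sg <- sample_trilinear_grad_cpp(mdat, mdim, vox, 0)
        Gw <- sweep(sg[, 2:4, drop = FALSE], 2, sp, "/") %*% t(orr)
        r <- sg[, 1] - Tk
        g <- numeric(6)
        dR <- euler_derivatives(p[1:3])
        for (i in 1:3)
          g[i] <- 2 * vv * sum(r * rowSums(Gw * (Xck %*% t(dR[[i]]))))
        g[4:6] <- 2 * vv * colSums(r * Gw)
        g
      }
      list(fn = fn, gr = gr)
    }
    if (l == 1 && is.null(init)) p <- rep(0, 6)
    keep <- inside_at(p)
    # safeguard across re-freezing passes: objectives on different
    # inclusion sets are not comparable, so track the best estimate by
    # mean per-included-sample residual and require a sane inclusion
    # fraction; revert if a pass makes things worse
    score_at <- function(p) {
      k <- inside_at(p)
      if (sum(k) < max(20, 0.4 * length(Tv))) return(Inf)
      make_obj(k)$fn(p) / sum(k)
    }
    p_best <- p; s_best <- score_at(p)
    for (pass in 1:3) {
      if (sum(keep) < 20) break
      obj <- make_obj(keep)
      res <- stats::optim(p, obj$fn, obj$gr, method = "BFGS",
                          control = list(maxit = max_iter, reltol = 1e-11,
                                         parscale = c(rep(0.02, 3),
                                                      rep(1, 3))))
      p <- res$par
      s_new <- score_at(p)
      if (s_new < s_best) { p_best <- p; s_best <- s_new }
      keep_new <- inside_at(p)
      if (mean(keep_new != keep) < 1e-3) break
      keep <- keep_new
    }
    p <- p_best
    if (l == length(pyr)) {
      k <- inside_at(p)
      obj <- make_obj(k)
      obj_identity <- obj$fn(rep(0, 6))
      obj_sol <- obj$fn(p)
      if (score_at(rep(0, 6)) < s_best) { p <- rep(0, 6); obj_sol <- obj_identity }
    }
  }
  out <- rigid_transform(p[1:3], p[4:6], center)
  attr(out, "objective") <- c(identity = obj_identity, solution = obj_sol)
  out
}

euler_derivatives <- function(angles) {
  ca <- cos(angles[1]); sa <- sin(angles[1])
  cb <- cos(angles[2]); sb <- sin(angles[2])
  cc <- cos(angles[3]); sc <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca))
  Ry <- rbind(c(cb, 0, sb), c(0, 1, 0), c(-sb, 0, cb))
  Rz <- rbind(c(cc, -sc, 0), c(sc, cc, 0), c(0, 0, 1))
  dRx <- rbind(c(0, 0, 0), c(0, -sa, -ca), c(0, ca, -sa))
  dRy <- rbind(c(-sb, 0, cb), c(0, 0, 0), c(-cb, 0, -sb))
  dRz <- rbind(c(-sc, -cc, 0), c(cc, -sc, 0), c(0, 0, 0))
  list(Rz %*% Ry %*% dRx, Rz %*% dRy %*% Rx, dRz %*% Ry %*% Rx)
}
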