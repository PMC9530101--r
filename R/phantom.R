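#' Specification of a synthetic knee phantom
#'
#' Describes a digital knee phantom: a tibial plateau (an elliptical
#' segment with an anterior tuberosity lobe and smooth trabecular-like
#' internal texture, so that bone-anchored rigid registration is
#' well-posed) topped by two crescent-shaped menisci (annulus sectors in
#' the plateau plane), on an anisotropic voxel grid centred on the joint.  The default
#' resolution mirrors a high-resolution 3D gradient-echo knee protocol
#' (0.6 x 0.6 x 0.5 mm).  The medial meniscus is modelled with a larger
#' radius and wider angular span than the lateral one, and each crescent
#' opens towards the joint midline, so anterior/intermediate/posterior horn
#' labelling is anatomically meaningful.
#'
#' @param shape Grid size (voxels) per axis.
#' @param spacing Voxel size (mm) per axis.
#' @param laterality `"right"` or `"left"` knee; decides which side of the
#'   midline the lateral meniscus occupies (world frame is RAS).
#' @param tibia_radius,tibia_height Cylinder radius / height (mm) of the
#'   tibial segment; its top face is the plateau plane.
#' @param plateau_z World z (mm) of the plateau surface.
#' @param meniscus_lift Cartilage gap (mm) between plateau and meniscus
#'   undersurface.
#' @param menisci Named list (`MM`, `LM`) of per-meniscus geometry:
#'   `center_offset` (in-plane mm, distance of the crescent centre from the
#'   midline, positive number), `r_inner`, `r_outer` (mm), `span_deg`
#'   (angular span, must lie in (10, 350)), `thickness` (mm).
#' @param intensities Named tissue means (`background`, `tibia`,
#'   `meniscus`), arbitrary units.
#' @param noise_sd Gaussian intensity noise SD as a fraction of the
#'   background-to-bone contrast (default 2 %).
#' @export
phantom_spec <- function(shape = c(96, 96, 64), spacing = c(0.6, 0.6, 0.5),
                         laterality = c("right", "left"),
                         tibia_radius = 22, tibia_height = 10,
                         plateau_z = -4, meniscus_lift = 1.5,
                         menisci = list(
                           MM = list(center_offset = 13, r_inner = 4.5,
                                     r_outer = 9, span_deg = 300,
                                     thickness = 3.5),
                           LM = list(center_offset = 13, r_inner = 4,
                                     r_outer = 8, span_deg = 250,
                                     thickness = 3.5)),
                         intensities = c(background = 50, tibia = 100,
                                         meniscus = 30),
                         noise_sd = 0.02) {
  laterality <- match.arg(laterality)
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3L, all(shape >= 8), length(spacing) == 3L,
            all(spacing > 0))
  for (m in c("MM", "LM")) {
    g <- menisci[[m]]
    if (is.null(g)) stop("menisci spec must contain ", m)
    if (g$span_deg <= 10 || g$span_deg >= 350)
      stop(m, ": angular span must lie strictly inside (10, 350) degrees ",
           "(a closed annulus has no arch endpoints)")
    if (g$r_inner <= 0 || g$r_outer <= g$r_inner)
      stop(m, ": need 0 < r_inner < r_outer")
  }
  spec <- structure(list(shape = shape, spacing = spacing,
                         laterality = laterality,
                         tibia_radius = tibia_radius,
                         tibia_height = tibia_height,
                         plateau_z = plateau_z,
                         meniscus_lift = meniscus_lift,
                         menisci = menisci, intensities = intensities,
                         noise_sd = noise_sd),
                    class = "phantom_spec")
  # fit check: crescents must stay >= 3 voxels inside the grid
  half <- (shape - 1) * spacing / 2
  margin <- 3 * spacing
  for (m in c("MM", "LM")) {
    g <- menisci[[m]]
    reach <- g$center_offset + g$r_outer
    ztop <- plateau_z + meniscus_lift + g$thickness
    if (reach > half[1] - margin[1] || reach > half[2] - margin[2] ||
        ztop > half[3] - margin[3])
      stop(m, " does not fit inside the grid with a 3-voxel margin")
  }
  spec
}

phantom_geometry <- function(spec) {
  origin <- -(spec$shape - 1) * spec$spacing / 2
  knee_volume(array(0, spec$shape), spec$spacing, origin, diag(3))
}

meniscus_center <- function(spec, m) {
  side <- if (spec$laterality == "right") 1 else -1
  # LM sits on the lateral side (+x for a right knee), MM on the medial side
  sx <- if (m == "LM") side else -side
  c(sx * spec$menisci[[m]]$center_offset, 0)
}

# Analytic phantom content at arbitrary world coordinates: tissue
# predicates and noiseless intensity.  Having this as a function of
# coordinates (not an image to be interpolated) lets moved positions be
# re-rendered exactly, as re-scanning the knee would.
phantom_content <- function(spec, P) {
  z0 <- spec$plateau_z

  # tibial segment: elliptical plateau (ML wider than AP, as on a real
  # tibia) with an anterior tuberosity lobe slightly off the midline --
  # the azimuthal asymmetry that makes tibia-anchored rigid registration
  # well-posed (a rotationally symmetric bone would leave the in-plane
  # rotation unidentifiable)
  rx <- spec$tibia_radius; ry <- 0.85 * spec$tibia_radius
  zin <- (P[, 3] <= z0) & (P[, 3] >= z0 - spec$tibia_height)
  ell <- (P[, 1] / rx)^2 + (P[, 2] / ry)^2 <= 1
  lobe <- ((P[, 1] - 0.2 * rx)^2 + (P[, 2] - 1.0 * ry)^2) <= (0.35 * rx)^2
  tib <- (ell | lobe) & zin

  men <- list()
  for (m in c("MM", "LM")) {
    g <- spec$menisci[[m]]
    ctr <- meniscus_center(spec, m)
    dx <- P[, 1] - ctr[1]; dy <- P[, 2] - ctr[2]
    r <- sqrt(dx^2 + dy^2)
    # crescent opens towards the midline: accepted angles are within
    # span/2 of the away-from-midline direction
    away <- atan2(0, sign(ctr[1]))
    dang <- abs(((atan2(dy, dx) - away + pi) %% (2 * pi)) - pi)
    zb <- z0 + spec$meniscus_lift
    men[[m]] <- (r >= g$r_inner) & (r <= g$r_outer) &
      (dang <= g$span_deg / 2 * pi / 180) &
      (P[, 3] > zb) & (P[, 3] <= zb + g$thickness)
  }

  ints <- spec$intensities
  vals <- rep(ints[["background"]], nrow(P))
  # smooth trabecular-like intensity texture inside the bone gives the
  # masked SSD dense signal at every pyramid level; the aperiodic linear
  # and bilinear components prevent spurious matches one texture period
  # away (real trabecular structure repeats nowhere)
  tex <- 1 + 0.12 * sin(2 * pi * P[, 1] / 19) * sin(2 * pi * P[, 2] / 23) *
    sin(2 * pi * (P[, 3] + 0.3 * P[, 1]) / 17) +
    0.1 * P[, 1] / rx + 0.08 * P[, 1] * P[, 2] / (rx * ry)
  vals[tib] <- ints[["tibia"]] * tex[tib]
  vals[men$MM | men$LM] <- ints[["meniscus"]]
  list(tibia = tib, MM = men$MM, LM = men$LM, intensity = vals)
}

#' Generate a synthetic knee phantom
#'
#' Builds the template volume and the tibia / medial-meniscus /
#' lateral-meniscus masks of a [phantom_spec()].  Tissue voxels take
#' distinct intensity means plus seeded Gaussian noise; generation is
#' deterministic for a given spec and seed.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer RNG seed for the intensity noise.
#' @return List of class `knee_phantom`: `volume` (`knee_volume`), `tibia`,
#'   `MM`, `LM` (`label_mask`), the grid-fixed `noise` field, and the
#'   `spec`.
#' @export
make_phantom <- function(spec = phantom_spec(), seed = 1) {
  geom <- phantom_geometry(spec)
  X <- grid_world_coords(geom)
  ct <- phantom_content(spec, X)

  contrast <- max(spec$intensities) - min(spec$intensities)
  if (!is.null(seed)) set.seed(seed)
  noise <- stats::rnorm(nrow(X), sd = spec$noise_sd * contrast)

  vol <- knee_volume(array(ct$intensity + noise, spec$shape), spec$spacing,
                     geom$origin)
  mk <- function(v, name) label_mask(array(as.numeric(v), spec$shape),
                                     spec$spacing, geom$origin,
                                     label_name = name)
  structure(list(volume = vol,
                 tibia = mk(ct$tibia, "tibia"),
                 MM = mk(ct$MM, "meniscus_medial"),
                 LM = mk(ct$LM, "meniscus_lateral"),
                 noise = noise,
                 spec = spec),
            class = "knee_phantom")
}

#' @export
print.knee_phantom <- function(x, ...) {
  cat("<knee_phantom>", paste(x$spec$shape, collapse = " x "), "voxels,",
      x$spec$laterality, "knee\n")
  cat("  tibia:", sum(x$tibia$data), " MM:", sum(x$MM$data),
      " LM:", sum(x$LM$data), "voxels\n")
  invisible(x)
}

#' Ground-truth motion for a phantom
#'
#' The composed motion is `phi(x) = A(x + u_loc(x))` with `A` the rigid part
#' (whole-knee repositioning composed with an in-plane tibial rotation about
#' the plateau centre) and `u_loc` a smooth local field: per-meniscus
#' in-plane translations applied through compact spatial windows that equal
#' 1 on the owning meniscus and 0 on the tibia, plus an optional Gaussian
#' displacement bump.  Because `u_loc` vanishes on the tibia, the motion of
#' the menisci *relative to the tibia frame* — what the registration
#' pipeline measures after rigid alignment — is exactly `u_loc`.
#'
#' @param global_rigid A [rigid_transform()] for whole-knee repositioning.
#' @param tibial_rotation_deg In-plane rotation (degrees, about the world z
#'   axis through the plateau centre) mimicking internal/external tibial
#'   rotation under torque.
#' @param meniscus_translation Named list (`MM`, `LM`) of length-3 world
#'   translations in mm; the z component must be 0 (in-plane gliding).
#' @param bump Optional list `(center, width, amplitude)`: Gaussian
#'   displacement bump `amplitude * exp(-|x - center|^2 / (2 width^2))`,
#'   amplitude a length-3 mm vector with norm at most 8.
#' @param window_width Ramp length (mm) over which each per-meniscus window
#'   falls smoothly (C1 smoothstep) from 1 to exactly 0; the window is
#'   exactly 1 within `window_plateau` of the owning meniscus and exactly 0
#'   beyond `window_plateau + window_width`, so menisci further apart than
#'   that receive no cross-talk.  Larger ramps permit larger translations
#'   (the in-plane displacement gradient is bounded by
#'   `1.5 * |t| / window_width`).
#' @param window_plateau Distance (mm) from the meniscus surface within
#'   which the window stays exactly 1.
#' @export
ground_truth_motion <- function(global_rigid = rigid_transform(),
                                tibial_rotation_deg = 0,
                                meniscus_translation = list(MM = c(0, 0, 0),
                                                            LM = c(0, 0, 0)),
                                bump = NULL,
                                window_width = 18, window_plateau = 1) {
  for (m in c("MM", "LM")) {
    t <- meniscus_translation[[m]]
    if (length(t) != 3L || any(!is.finite(t)))
      stop("meniscus_translation$", m, " must be a finite length-3 vector")
    if (abs(t[3]) > 1e-9)
      stop("meniscus translations must be in-plane (z component 0)")
  }
  # invertibility: the composed in-plane displacement must be a contraction
  slope <- max(vapply(meniscus_translation, function(t) sqrt(sum(t^2)),
                      numeric(1))) * 1.5 / window_width
  if (!is.null(bump)) {
    if (sqrt(sum(bump$amplitude^2)) > 8)
      stop("bump amplitude must not exceed 8 mm")
    slope <- slope + sqrt(sum(bump$amplitude^2)) * exp(-0.5) / bump$width
  }
  if (slope >= 0.95)
    stop("motion is not invertible: displacement gradient bound ",
         signif(slope, 3), " >= 0.95; reduce amplitudes or widen windows")
  structure(list(global_rigid = global_rigid,
                 tibial_rotation_deg = tibial_rotation_deg,
                 meniscus_translation = meniscus_translation,
                 bump = bump, window_width = window_width,
                 window_plateau = window_plateau),
            class = "ground_truth_motion")
}

smoothstep01 <- function(s) {
  s <- pmin(1, pmax(0, s))
  3 * s^2 - 2 * s^3
}

has_local_motion <- function(motion) {
  any(vapply(motion$meniscus_translation,
             function(t) any(t != 0), logical(1))) || !is.null(motion$bump)
}

# per-meniscus window grids on the template grid (exactly 1 on the owning
# meniscus, exactly 0 at and below the plateau); NULL when the motion has
# no local component (pure rigid repositioning)
motion_windows <- function(phantom, motion) {
  if (!has_local_motion(motion)) return(NULL)
  spec <- phantom$spec
  z0 <- spec$plateau_z
  lift <- spec$meniscus_lift
  X <- grid_world_coords(phantom$volume)
  zgate <- smoothstep01((X[, 3] - z0) / lift)
  out <- list()
  for (m in c("MM", "LM")) {
    dmap <- as.numeric(euclidean_distance_map(phantom[[m]])$data)
    dd <- (dmap - motion$window_plateau) / motion$window_width
    out[[m]] <- (1 - smoothstep01(dd)) * zgate
  }
  out
}

# local (relative-to-tibia) displacement at arbitrary world points, using
# precomputed window grids
local_displacement <- function(points, windows, phantom, motion) {
  u <- matrix(0, nrow(points), 3)
  if (is.null(windows)) return(u)
  geom <- phantom$volume
  vox <- world_to_voxel(geom, points)
  d <- dim(geom$data)
  for (m in c("MM", "LM")) {
    t <- motion$meniscus_translation[[m]]
    if (all(t == 0)) next
    w <- sample_trilinear_cpp(windows[[m]], d, vox, 0)
    u <- u + outer(w, t)
  }
  if (!is.null(motion$bump)) {
    b <- motion$bump
    r2 <- rowSums(sweep(points, 2, b$center, "-")^2)
    u <- u + outer(exp(-r2 / (2 * b$width^2)), as.numeric(b$amplitude))
  }
  u
}

rigid_part <- function(phantom, motion) {
  z0 <- phantom$spec$plateau_z
  tibrot <- rigid_transform(angles = c(0, 0, motion$tibial_rotation_deg * pi / 180),
                            center = c(0, 0, z0))
  rigid_compose(motion$global_rigid, tibrot)
}

#' Apply a ground-truth motion to a phantom
#'
#' Generates the moving volume and masks by evaluating the phantom's
#' analytic content at positions pulled back through the inverse of the
#' composed motion (fixed-point inversion of the local part, exact
#' inversion of the rigid part), so that the forward displacement field on
#' the template grid is returned exactly.  Re-rendering analytically —
#' rather than interpolating the template image — emulates scanning the
#' knee in its new position: tissue boundaries stay crisp and the scanner
#' noise field stays fixed to the grid.
#'
#' @param phantom A [make_phantom()] result.
#' @param motion A [ground_truth_motion()].
#' @return List of class `moved_phantom`: `volume`, `tibia`, `MM`, `LM`
#'   (moving images), `truth_field` (full forward motion, mm, template
#'   grid), `truth_relative` (motion relative to the tibia frame, i.e. the
#'   field the pipeline should recover after rigid alignment), `motion`,
#'   and `rigid_truth` (the composed rigid part).
#' @export
apply_motion <- function(phantom, motion) {
  geom <- phantom$volume
  d <- dim(geom$data)
  X <- grid_world_coords(geom)
  windows <- motion_windows(phantom, motion)
  A <- rigid_part(phantom, motion)

  u_loc <- local_displacement(X, windows, phantom, motion)
  fwd <- rigid_apply(A, X + u_loc)
  truth_field <- deformation_field(fwd - X, geom)
  truth_relative <- deformation_field(u_loc, geom)

  # inverse: x solves x = A^{-1}(y) - u_loc(x); u_loc has zero z component
  # so the z coordinate is exact after the first iteration and the in-plane
  # update is a contraction.  Iterate only over voxels whose trajectory can
  # reach the windows' compact support (the rest have u_loc = 0 exactly).
  Ainv <- rigid_invert(A)
  Yb <- rigid_apply(Ainv, X)  # A^{-1}(grid points)
  x <- Yb
  if (!is.null(windows)) {
    reach <- max(vapply(motion$meniscus_translation,
                        function(t) sqrt(sum(t^2)), numeric(1)))
    if (!is.null(motion$bump))
      reach <- reach + sqrt(sum(motion$bump$amplitude^2))
    wsup <- pmax(windows$MM, windows$LM) > 0
    dsup <- edt3d_cpp(as.numeric(wsup), d, geom$spacing)
    dY <- sample_trilinear_cpp(dsup, d, world_to_voxel(geom, Yb),
                               max(dsup))
    act <- which(dY <= reach + max(geom$spacing))
    xa <- Yb[act, , drop = FALSE]
    for (it in 1:40) {
      xa_new <- Yb[act, , drop = FALSE] -
        local_displacement(xa, windows, phantom, motion)
      if (max(abs(xa_new - xa)) < 1e-7) { xa <- xa_new; break }
      xa <- xa_new
    }
    x[act, ] <- xa
  }
  # re-render the phantom content at the pulled-back positions, as if the
  # knee had been scanned in the new position: tissue predicates and bone
  # texture are evaluated analytically (no interpolation of the template
  # image, which would blur edges direction-dependently and bias
  # registration tests), while the scanner noise field stays on the grid
  ct <- phantom_content(phantom$spec, x)
  vol <- knee_volume(array(ct$intensity + phantom$noise, d),
                     geom$spacing, geom$origin, geom$orientation)
  mk <- function(v, name) label_mask(array(as.numeric(v), d), geom$spacing,
                                     geom$origin, geom$orientation,
                                     label_name = name)
  structure(list(volume = vol,
                 tibia = mk(ct$tibia, "tibia"),
                 MM = mk(ct$MM, "meniscus_medial"),
                 LM = mk(ct$LM, "meniscus_lateral"),
                 truth_field = truth_field,
                 truth_relative = truth_relative,
                 motion = motion, rigid_truth = A),
            class = "moved_phantom")
}

#' Analytic per-segment ground-truth motion
#'
#' Computes the relative-to-tibia mean motion of each meniscus segment
#' directly from the motion parameters (window values at the segment's
#' voxel centres), without constructing a dense deformation field — an
#' independent code path used to validate [crop_field()] +
#' [segment_motion()] on the stored truth field.
#'
#' @param phantom A [make_phantom()] result.
#' @param motion A [ground_truth_motion()].
#' @param labels_list Named list (`MM`, `LM`) of [partition_arch()] labels.
#' @param axes A [anatomical_axes()] result.
#' @return Tidy data.frame: meniscus, segment, avg_mm, ml_mm, ap_mm,
#'   n_voxels.
#' @export
ground_truth_segment_motion <- function(phantom, motion, labels_list, axes) {
  windows <- motion_windows(phantom, motion)
  rows <- list()
  for (m in c("MM", "LM")) {
    labs <- labels_list[[m]]
    segs <- list(AH = 1L, IH = 2L, PH = 3L, whole = 1:3)
    for (nm in names(segs)) {
      idx <- which(labs$data %in% segs[[nm]] & labs$data > 0)
      I0 <- grid_index_matrix(dim(labs$data))[idx, , drop = FALSE]
      P <- voxel_to_world(labs, I0)
      ubar <- colMeans(local_displacement(P, windows, phantom, motion))
      rows[[length(rows) + 1]] <-
        data.frame(meniscus = m, segment = nm,
                   avg_mm = sqrt(sum(ubar^2)),
                   ml_mm = sum(ubar * axes$ml_axis),
                   ap_mm = sum(ubar * axes$ap_axis),
                   n_voxels = length(idx))
    }
  }
  do.call(rbind, rows)
}
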