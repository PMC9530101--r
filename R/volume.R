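#' @useDynLib meniscusmotion, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' 3D image volume with world-coordinate geometry
#'
#' A `knee_volume` couples a 3D scalar array with its voxel grid geometry:
#' per-axis voxel size (mm), the world position of voxel `(0,0,0)` and a 3x3
#' orthonormal direction matrix mapping voxel axes to patient axes.  All
#' coordinates refer to voxel centres, indices are 0-based in the
#' voxel-to-world mapping (the NIfTI convention), and world coordinates are
#' in mm (RAS: +x right, +y anterior, +z superior).
#'
#' @param data 3D numeric array.
#' @param spacing Length-3 positive voxel size in mm.
#' @param origin Length-3 world position (mm) of voxel `(0,0,0)`.
#' @param orientation 3x3 orthonormal direction matrix.
#' @return An object of class `knee_volume`.
#' @export
knee_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        orientation = diag(3)) {
  data <- squeeze_to_3d(data)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  orientation <- as.matrix(orientation)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  check_orientation(orientation)
  structure(list(data = data, spacing = spacing, origin = origin,
                 orientation = orientation),
            class = "knee_volume")
}

check_orientation <- function(orientation, tol = 1e-6) {
  if (!is.matrix(orientation) || any(dim(orientation) != c(3L, 3L)))
    stop("`orientation` must be a 3x3 matrix")
  if (max(abs(crossprod(orientation) - diag(3))) > tol)
    stop("`orientation` must be orthogonal (columns unit-norm and pairwise orthogonal)")
  invisible(orientation)
}

squeeze_to_3d <- function(data) {
  d <- dim(data)
  if (is.null(d)) stop("volume data must be a 3D array")
  if (length(d) > 3L) {
    extra <- d[-(1:3)]
    if (any(extra != 1L))
      stop("volume has ", length(d), " non-singleton dimensions; only 3D images are supported")
    data <- array(data, dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("volume must be 3D, got ", length(d), " dimensions")
  # strip any foreign attributes (e.g. niftiImage internals)
  array(as.numeric(data), d)
}

#' Binary label mask on a volume grid
#'
#' A `label_mask` is a `knee_volume` whose data are strictly 0/1, carrying
#' the anatomical label name it represents.
#'
#' @param data 3D array coercible to 0/1.
#' @param label_name Label, e.g. `"tibia"`, `"meniscus_medial"`,
#'   `"meniscus_lateral"`.
#' @inheritParams knee_volume
#' @return An object of class `c("label_mask", "knee_volume")`.
#' @export
label_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       orientation = diag(3), label_name = "mask") {
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1)))
    stop("mask values must be 0/1")
  vol <- knee_volume(data, spacing, origin, orientation)
  vol$label_name <- label_name
  class(vol) <- c("label_mask", "knee_volume")
  vol
}

#' Convert a volume to a mask by thresholding at 0.5
#' @param vol A `knee_volume`.
#' @param label_name Label to attach.
#' @export
as_label_mask <- function(vol, label_name = "mask") {
  label_mask((vol$data > 0.5) * 1, vol$spacing, vol$origin, vol$orientation,
             label_name = label_name)
}

#' @export
print.knee_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  if (!is.null(x$label_name))
    cat("  label:", x$label_name, " foreground voxels:", sum(x$data > 0.5), "\n")
  cat("  origin (mm):", paste(signif(x$origin, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Voxel-to-world affine of a volume
#'
#' @param vol A `knee_volume`.
#' @return 4x4 affine mapping 0-based voxel indices to world mm.
#' @export
vox2world_affine <- function(vol) {
  A <- diag(4)
  A[1:3, 1:3] <- vol$orientation %*% diag(vol$spacing)
  A[1:3, 4] <- vol$origin
  A
}

#' Map 0-based voxel indices to world coordinates (mm)
#' @param vol A `knee_volume`.
#' @param idx n x 3 matrix of 0-based (possibly fractional) voxel indices.
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(idx %*% diag(vol$spacing) %*% t(vol$orientation), 2, vol$origin, "+")
}

#' Map world coordinates (mm) to 0-based voxel indices
#' @param vol A `knee_volume`.
#' @param xyz n x 3 matrix of world coordinates.
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(xyz, 2, vol$origin, "-") %*% vol$orientation %*% diag(1 / vol$spacing)
}

#' All voxel-centre world coordinates of a grid
#' @param vol A `knee_volume`.
#' @return n x 3 matrix in array (column-major) order.
#' @export
grid_world_coords <- function(vol) {
  voxel_to_world(vol, grid_index_matrix(dim(vol$data)))
}

grid_index_matrix <- function(d) {
  cbind(rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
        rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
        rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
}

#' Voxel volume in mm^3
#' @param vol A `knee_volume`.
#' @export
voxel_volume <- function(vol) prod(vol$spacing)

#' Test whether two volumes share the same grid
#' @param a,b `knee_volume` objects.
#' @param tol Absolute tolerance on geometry entries.
#' @export
same_grid <- function(a, b, tol = 1e-5) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$orientation - b$orientation)) <= tol
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop(what, " are not defined on the same grid (shape/spacing/origin/orientation)")
  invisible(TRUE)
}

#' Load a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file and reconstructs the grid geometry from its affine
#' (sform preferred).  Trailing singleton dimensions are squeezed; files
#' with fewer than 3 or more than 3 non-singleton dimensions are rejected.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A `knee_volume`.
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  data <- squeeze_to_3d(as.array(img))
  M <- aff[1:3, 1:3, drop = FALSE]
  spacing <- sqrt(colSums(M^2))
  if (any(spacing <= 0)) stop("degenerate affine in ", path)
  orientation <- sweep(M, 2, spacing, "/")
  check_orientation(orientation, tol = 1e-4)
  # re-orthonormalise to remove float32 storage noise
  sv <- svd(orientation)
  orientation <- sv$u %*% t(sv$v)
  knee_volume(data, spacing = spacing, origin = aff[1:3, 4],
              orientation = orientation)
}

#' Load a binary label mask from NIfTI
#'
#' If a YAML sidecar `<path minus extension>.yaml` exists and names a
#' `label`, it is attached; otherwise `label_name` is used.
#'
#' @inheritParams load_volume
#' @param label_name Fallback label name.
#' @return A `label_mask`.
#' @export
load_mask <- function(path, label_name = NULL) {
  vol <- load_volume(path)
  side <- sidecar_path(path)
  if (is.null(label_name) && file.exists(side)) {
    meta <- yaml::read_yaml(side)
    if (!is.null(meta$label)) label_name <- meta$label
  }
  if (is.null(label_name)) label_name <- "mask"
  as_label_mask(vol, label_name = label_name)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".yaml")
}

#' Save a volume or mask as NIfTI-1
#'
#' Volumes are stored as float64 so that save/load roundtrips are lossless;
#' masks as uint8 with a YAML sidecar naming the label.
#'
#' @param vol A `knee_volume` or `label_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
save_volume <- function(vol, path) {
  is_mask <- inherits(vol, "label_mask")
  img <- RNifti::asNifti(vol$data)
  aff <- vox2world_affine(vol)
  RNifti::`sform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::writeNifti(img, path,
                     datatype = if (is_mask) "uint8" else "double")
  if (is_mask)
    yaml::write_yaml(list(label = vol$label_name), sidecar_path(path))
  invisible(path)
}

#' Euclidean distance map of a mask
#'
#' Computes, for every voxel, the exact spacing-aware Euclidean distance in
#' mm to the nearest foreground voxel centre (0 on the foreground itself),
#' using the separable lower-envelope algorithm.
#'
#' @param mask A `label_mask` with at least one foreground voxel.
#' @return A `knee_volume` of distances (mm) on the same grid.
#' @export
euclidean_distance_map <- function(mask) {
  if (sum(mask$data > 0.5) == 0L)
    stop("mask is empty: distance map undefined")
  d <- edt3d_cpp(as.numeric(mask$data), dim(mask$data), mask$spacing)
  knee_volume(array(d, dim(mask$data)), mask$spacing, mask$origin,
              mask$orientation)
}

#' Gaussian smoothing of a volume (sigma in voxels)
#' @param vol A `knee_volume`.
#' @param sigma Scalar or per-axis sigma in voxel units.
#' @export
smooth_volume <- function(vol, sigma = 1) {
  sigma <- rep_len(as.numeric(sigma), 3)
  out <- gaussian_smooth_cpp(as.numeric(vol$data), dim(vol$data), sigma)
  knee_volume(array(out, dim(vol$data)), vol$spacing, vol$origin,
              vol$orientation)
}

#' Downsample a volume by 2 with Gaussian anti-aliasing
#'
#' Keeps every second voxel starting at index 0, after smoothing with
#' sigma = 1 voxel; the world position of voxel 0 is unchanged and the
#' spacing doubles, so the coarse grid is geometrically consistent.
#'
#' @param vol A `knee_volume`.
#' @param smooth If `FALSE`, subsample without anti-alias smoothing.
#' @export
downsample2 <- function(vol, smooth = TRUE) {
  v <- if (smooth) smooth_volume(vol, 1) else vol
  d <- dim(v$data)
  ii <- seq(1, d[1], by = 2); jj <- seq(1, d[2], by = 2); kk <- seq(1, d[3], by = 2)
  knee_volume(v$data[ii, jj, kk, drop = FALSE], vol$spacing * 2, vol$origin,
              vol$orientation)
}
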