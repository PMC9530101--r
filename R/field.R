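#' Dense deformation field on a template grid
#'
#' Stores a per-voxel 3-vector displacement in mm (world frame) on the
#' template grid.  Sampling the moving image at `x + u(x)` for template
#' voxel centres `x` pulls the moving position back onto the template, so
#' `u` describes the motion of each template voxel into the moving position.
#'
#' @param u n x 3 matrix (array order) or `dim x 3` 4D array of
#'   displacements in mm.
#' @param geometry A `knee_volume` (or compatible) defining the grid.
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(u, geometry) {
  d <- dim(geometry$data)
  n <- prod(d)
  if (is.matrix(u)) {
    if (nrow(u) != n || ncol(u) != 3L) stop("`u` must be n x 3 for this grid")
  } else {
    du <- dim(u)
    if (length(du) != 4L || any(du[1:3] != d) || du[4] != 3L)
      stop("`u` must be a dim x 3 array matching the grid")
    u <- matrix(u, ncol = 3)
  }
  if (any(!is.finite(u))) stop("deformation field must be finite everywhere")
  structure(list(u = u,
                 geometry = list(dim = d, spacing = geometry$spacing,
                                 origin = geometry$origin,
                                 orientation = geometry$orientation)),
            class = "deformation_field")
}

field_matrix <- function(field) field$u

field_geometry <- function(field) {
  g <- field$geometry
  knee_volume(array(0, g$dim), g$spacing, g$origin, g$orientation)
}

#' @export
print.deformation_field <- function(x, ...) {
  g <- x$geometry
  mag <- sqrt(rowSums(x$u^2))
  cat(sprintf("<deformation_field> %d x %d x %d grid, |u| max %.3g mm, mean %.3g mm\n",
              g$dim[1], g$dim[2], g$dim[3], max(mag), mean(mag)))
  invisible(x)
}

#' Save a deformation field as a 3-component NIfTI image
#' @param field A `deformation_field`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @export
save_field <- function(field, path) {
  g <- field$geometry
  arr <- array(field$u, c(g$dim, 3))
  img <- RNifti::asNifti(arr)
  A <- diag(4); A[1:3, 1:3] <- g$orientation %*% diag(g$spacing); A[1:3, 4] <- g$origin
  RNifti::`sform<-`(img, structure(A, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(A, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Load a deformation field saved by [save_field()]
#' @param path NIfTI path holding a `dim x 3` displacement image.
#' @export
load_field <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L || dim(arr)[4] != 3L)
    stop("not a 3-component displacement image: ", path)
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  M <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  geom <- knee_volume(array(0, dim(arr)[1:3]), spacing, aff[1:3, 4],
                      sweep(M, 2, spacing, "/"))
  deformation_field(arr, geom)
}

#' Sample a deformation field at world points (trilinear per component)
#' @param field A `deformation_field`.
#' @param xyz n x 3 world coordinates (mm).
#' @export
sample_field <- function(field, xyz) {
  g <- field$geometry
  geom <- field_geometry(field)
  vox <- world_to_voxel(geom, xyz)
  out <- matrix(0, nrow(vox), 3)
  for (cmp in 1:3)
    out[, cmp] <- sample_trilinear_cpp(field$u[, cmp], g$dim, vox, 0)
  out
}
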