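#' Crop a deformation field with a meniscus mask
#'
#' Restricts the dense field to the template-meniscus voxels, returning the
#' displacements unmodified.
#'
#' @param u A `deformation_field`.
#' @param meniscus Non-empty `label_mask` on the field's grid.
#' @return A data.frame with 0-based voxel indices `i, j, k`, world
#'   coordinates `x, y, z` (mm) and displacements `ux, uy, uz` (mm).
#' @export
crop_field <- function(u, meniscus) {
  stop_if_grid_mismatch(field_geometry(u), meniscus, "field and mask")
  idx <- which(meniscus$data > 0.5)
  if (!length(idx)) stop("meniscus mask is empty")
  I0 <- grid_index_matrix(dim(meniscus$data))[idx, , drop = FALSE]
  X <- voxel_to_world(meniscus, I0)
  U <- field_matrix(u)[idx, , drop = FALSE]
  data.frame(i = I0[, 1], j = I0[, 2], k = I0[, 3],
             x = X[, 1], y = X[, 2], z = X[, 3],
             ux = U[, 1], uy = U[, 2], uz = U[, 3])
}

#' Per-segment mean motion of a meniscus
#'
#' For each arc-length segment (AH, IH, PH) and for the whole meniscus,
#' averages the displacement vectors of the member voxels and reports the
#' norm of the mean vector (`avg_mm`) together with its signed projections
#' on the anatomical axes: `ml_mm` (positive = lateral) and `ap_mm`
#' (positive = posterior).
#'
#' @param u A `deformation_field` on the template grid.
#' @param labels A [partition_arch()] result on the same grid.
#' @param axes A [anatomical_axes()] result.
#' @param meniscus_id `"MM"` or `"LM"` (carried through to the output).
#' @return A data.frame of class `segment_motion` with one row per segment
#'   (`AH`, `IH`, `PH`, `whole`) and columns `meniscus, segment, avg_mm,
#'   ml_mm, ap_mm, n_voxels`.
#' @export
segment_motion <- function(u, labels, axes, meniscus_id = "MM") {
  stop_if_grid_mismatch(field_geometry(u), labels, "field and segment labels")
  U <- field_matrix(u)
  segs <- list(AH = 1L, IH = 2L, PH = 3L, whole = 1:3)
  rows <- lapply(names(segs), function(nm) {
    idx <- which(labels$data %in% segs[[nm]] & labels$data > 0)
    if (!length(idx)) stop("segment ", nm, " is empty")
    ubar <- colMeans(U[idx, , drop = FALSE])
    data.frame(meniscus = meniscus_id, segment = nm,
               avg_mm = sqrt(sum(ubar^2)),
               ml_mm = sum(ubar * axes$ml_axis),
               ap_mm = sum(ubar * axes$ap_axis),
               n_voxels = length(idx))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("segment_motion", class(out))
  out
}
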