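#' Anatomical AP/ML axes from PCA of the meniscus masks
#'
#' Fits the principal plane of the combined medial + lateral meniscus voxel
#' cloud (world coordinates, mm) via the top-2 eigenvectors of its
#' covariance.  Of the two in-plane eigenvectors, the one carrying the
#' larger projection of the inter-meniscus centroid difference becomes the
#' medio-lateral (ML) axis; the other becomes the anterior-posterior (AP)
#' axis.  Signs are fixed anatomically: ML points from the medial-meniscus
#' centroid towards the lateral-meniscus centroid (positive = lateral), AP
#' points posterior (negative patient-anterior direction in the RAS world
#' frame).  The laterality flag is used to cross-check that "lateral"
#' agrees with the patient's left/right side; a mismatch raises a warning
#' (typically swapped MM/LM masks).
#'
#' @param mm_mask,lm_mask Non-empty `label_mask`s of the medial and lateral
#'   meniscus on a common grid.
#' @param laterality `"left"` or `"right"` knee.
#' @return An object of class `meniscus_axes` with unit vectors `ap_axis`
#'   (positive = posterior), `ml_axis` (positive = lateral) and
#'   `plane_normal`.
#' @export
anatomical_axes <- function(mm_mask, lm_mask, laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  Xm <- mask_world_coords(mm_mask)
  Xl <- mask_world_coords(lm_mask)
  if (!nrow(Xm) || !nrow(Xl)) stop("meniscus masks must be non-empty")
  X <- rbind(Xm, Xl)
  S <- stats::cov(X)
  eig <- eigen(S, symmetric = TRUE)
  ev <- eig$values
  if ((ev[2] - ev[3]) / max(ev[1], .Machine$double.eps) < 1e-6)
    stop("degenerate voxel cloud: principal plane is not defined ",
         "(eigenvalue gap below 1e-6 relative)")
  e1 <- eig$vectors[, 1]; e2 <- eig$vectors[, 2]
  dcent <- colMeans(Xl) - colMeans(Xm)  # points medial -> lateral
  if (abs(sum(dcent * e1)) >= abs(sum(dcent * e2))) {
    ml <- e1; ap <- e2
  } else {
    ml <- e2; ap <- e1
  }
  s <- sum(dcent * ml)
  if (abs(s) < 1e-12)
    stop("inter-meniscus centroid difference is orthogonal to the principal plane")
  ml <- ml * sign(s)
  # positive AP = posterior = -anterior; world frame is RAS so anterior = +y
  posterior <- c(0, -1, 0)
  sa <- sum(ap * posterior)
  if (abs(sa) < 1e-8) {
    # AP nearly orthogonal to the patient AP axis: orient via a right-handed
    # (ml, ap, superior-ish normal) triple instead
    nrm <- cross3(ml, ap)
    if (nrm[3] < 0) ap <- -ap
  } else {
    ap <- ap * sign(sa)
  }
  nrm <- cross3(ml, ap)
  lat_dir <- if (laterality == "right") c(1, 0, 0) else c(-1, 0, 0)
  if (sum(ml * lat_dir) < 0)
    warning("ML axis points away from the ", laterality,
            "-knee lateral side; check mask labels / laterality flag")
  structure(list(ml_axis = ml, ap_axis = ap, plane_normal = nrm,
                 laterality = laterality),
            class = "meniscus_axes")
}

#' @export
print.meniscus_axes <- function(x, ...) {
  cat("<meniscus_axes>\n")
  cat("  ML (+lateral):  ", paste(signif(x$ml_axis, 4), collapse = ", "), "\n")
  cat("  AP (+posterior):", paste(signif(x$ap_axis, 4), collapse = ", "), "\n")
  cat("  normal:         ", paste(signif(x$plane_normal, 4), collapse = ", "), "\n")
  invisible(x)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

mask_world_coords <- function(mask) {
  idx <- which(mask$data > 0.5)
  voxel_to_world(mask, grid_index_matrix(dim(mask$data))[idx, , drop = FALSE])
}
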