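#' Partition a meniscus into three equal-arc-length segments
#'
#' Projects the crescent-shaped meniscus mask into the principal plane,
#' parameterises the arch by polar angle about the centre of the circle
#' fitted to the voxel cloud (algebraic least-squares fit; this origin
#' makes the polar parameterisation follow the arch, whereas the area
#' centroid sits far off the arc centre for wide-span crescents and skews
#' the end segments), accumulates arc length along the angularly ordered,
#' binned centreline (`ds = sqrt(dr^2 + (r dtheta)^2)`), and cuts at 1/3
#' and 2/3 of the total arc length.  The end containing the more anterior centreline endpoint
#' (smaller AP coordinate, since positive AP is posterior) is labelled the
#' anterior horn (AH), the opposite end the posterior horn (PH), the middle
#' the intermediate horn (IH).
#'
#' @param meniscus Non-empty, connected `label_mask` of one meniscus.
#' @param axes A [anatomical_axes()] result.
#' @param bin_deg Angular bin width (degrees) for the centreline.
#' @return A `segment_labels` object: a `knee_volume` whose data are 0
#'   (background), 1 (AH), 2 (IH), 3 (PH), with attribute `boundaries_deg`
#'   (the two cut angles, relative to the arch start) and `span_deg`.
#' @export
partition_arch <- function(meniscus, axes, bin_deg = 2) {
  idx <- which(meniscus$data > 0.5)
  if (!length(idx)) stop("meniscus mask is empty")
  lab <- label_components_cpp(as.numeric(meniscus$data), dim(meniscus$data))
  if (max(lab) > 1L)
    stop("meniscus mask is disconnected (", max(lab), " components)")

  X <- mask_world_coords(meniscus)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr, "-")
  q1 <- as.numeric(Xc %*% axes$ml_axis)
  q2 <- as.numeric(Xc %*% axes$ap_axis)
  cc <- fit_circle_center(q1, q2)
  p1 <- q1 - cc[1]
  p2 <- q2 - cc[2]
  theta <- atan2(p2, p1)

  # locate the angular gap (the crescent opening)
  ord <- order(theta)
  ts <- theta[ord]
  gaps <- c(diff(ts), ts[1] + 2 * pi - ts[length(ts)])
  gi <- which.max(gaps)
  if (gaps[gi] < 10 * pi / 180)
    stop("mask forms a closed annulus (largest angular gap < 10 degrees); ",
         "arch endpoints are undefined")
  start <- if (gi == length(ts)) ts[1] else ts[gi + 1]
  phi <- (theta - start) %% (2 * pi)
  span <- max(phi)

  # binned centreline: mean radius per angular bin
  h <- bin_deg * pi / 180
  nb <- max(3L, as.integer(ceiling(span / h)))
  bin <- pmin(nb, pmax(1L, as.integer(floor(phi / span * nb)) + 1L))
  r <- sqrt(p1^2 + p2^2)
  rbar <- tapply(r, factor(bin, levels = seq_len(nb)), mean)
  bmid <- (seq_len(nb) - 0.5) / nb * span
  keep <- !is.na(rbar)
  rbar <- as.numeric(rbar[keep]); bmid <- bmid[keep]
  # smooth the centreline radius: the per-bin voxel means carry
  # lattice-discretisation noise that would otherwise dominate |dr|
  rbar <- running_mean(rbar, half_width = 3L)

  dphi <- diff(bmid)
  dr <- diff(rbar)
  rmid <- (rbar[-1] + rbar[-length(rbar)]) / 2
  ds <- sqrt(dr^2 + (rmid * dphi)^2)
  s <- c(0, cumsum(ds))
  stot <- s[length(s)]
  cut_phi <- function(frac) {
    target <- frac * stot
    i <- findInterval(target, s, all.inside = TRUE)
    w <- (target - s[i]) / (s[i + 1] - s[i])
    bmid[i] + w * (bmid[i + 1] - bmid[i])
  }
  c1 <- cut_phi(1 / 3); c2 <- cut_phi(2 / 3)

  part <- ifelse(phi <= c1, 1L, ifelse(phi <= c2, 2L, 3L))

  # anterior end: compare AP coordinate of the two arch endpoints
  ap_start <- rbar[1] * sin(start + bmid[1])
  ap_end <- rbar[length(rbar)] * sin(start + bmid[length(bmid)])
  labels <- if (ap_start <= ap_end) c(1L, 2L, 3L) else c(3L, 2L, 1L)
  seg <- labels[part]

  out <- array(0L, dim(meniscus$data))
  out[idx] <- seg
  res <- knee_volume(out, meniscus$spacing, meniscus$origin,
                     meniscus$orientation)
  class(res) <- c("segment_labels", class(res))
  attr(res, "boundaries_deg") <- c(c1, c2) * 180 / pi
  attr(res, "span_deg") <- span * 180 / pi
  res
}

running_mean <- function(v, half_width = 3L) {
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half_width); hi <- min(n, i + half_width)
    out[i] <- mean(v[lo:hi])
  }
  out
}

# Algebraic (Kasa) least-squares circle fit; returns the centre.  Falls
# back to the centroid (origin of the input coordinates) if the normal
# equations are near-singular.
fit_circle_center <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  ctr <- tryCatch({
    sol <- qr.solve(A, b)
    sol[1:2]
  }, error = function(e) c(0, 0))
  if (any(!is.finite(ctr))) ctr <- c(0, 0)
  ctr
}

#' @export
print.segment_labels <- function(x, ...) {
  counts <- table(factor(x$data[x$data > 0], levels = 1:3,
                         labels = c("AH", "IH", "PH")))
  cat(sprintf("<segment_labels> span %.1f deg, cuts at %.1f / %.1f deg\n",
              attr(x, "span_deg"), attr(x, "boundaries_deg")[1],
              attr(x, "boundaries_deg")[2]))
  print(counts)
  invisible(x)
}
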