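# Shared fixture builders: all synthetic, generated in code.

# grid centred on the world origin
centred_grid <- function(d, spacing = c(1, 1, 1)) {
  knee_volume(array(0, d), spacing, origin = -(d - 1) * spacing / 2)
}

# annulus-sector crescent mask in the z = 0 plane of a centred grid:
# radii [r_in, r_out], angular span `span_deg` centred on direction
# `mid_deg`, thickness along z in [-zh, zh], optional in-plane shift
crescent_mask <- function(grid, r_in = 5, r_out = 10, span_deg = 270,
                          mid_deg = 90, zh = 2, shift = c(0, 0, 0),
                          center = c(0, 0)) {
  X <- grid_world_coords(grid)
  dx <- X[, 1] - center[1] - shift[1]
  dy <- X[, 2] - center[2] - shift[2]
  r <- sqrt(dx^2 + dy^2)
  dang <- abs(((atan2(dy, dx) - mid_deg * pi / 180 + pi) %% (2 * pi)) - pi)
  z <- X[, 3] - shift[3]
  m <- r >= r_in & r <= r_out & dang <= span_deg / 2 * pi / 180 &
    z >= -zh & z <= zh
  label_mask(array(as.numeric(m), dim(grid$data)), grid$spacing, grid$origin,
             grid$orientation)
}

# axes aligned with the world frame (ML = +x lateral, AP = -y posterior)
world_axes <- function() {
  structure(list(ml_axis = c(1, 0, 0), ap_axis = c(0, -1, 0),
                 plane_normal = c(0, 0, -1), laterality = "right"),
            class = "meniscus_axes")
}

# brute-force distance map oracle (all-pairs minimum), distances in mm
brute_force_edt <- function(mask) {
  d <- dim(mask$data)
  fg <- which(mask$data > 0.5, arr.ind = TRUE)
  W <- sweep(fg - 1, 2, mask$spacing, "*")
  all_idx <- which(array(TRUE, d), arr.ind = TRUE)
  A <- sweep(all_idx - 1, 2, mask$spacing, "*")
  out <- apply(A, 1, function(p) sqrt(min(colSums((t(W) - p)^2))))
  array(out, d)
}

# brute-force exact two-sided signed-rank p by enumerating sign assignments
brute_force_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.numeric(signs %*% rk)
  p_le <- mean(Ws <= W_obs)
  p_ge <- mean(Ws >= W_obs)
  min(1, 2 * min(p_le, p_ge))
}

dice_coef <- function(a, b) {
  2 * sum(a$data * b$data) / (sum(a$data) + sum(b$data))
}

# trapezoidal quadrature
trapz_int <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
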