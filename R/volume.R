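#' 3D scalar volume
#'
#' Lightweight container for a 3D scalar grid with per-axis physical spacing.
#' The array is indexed `[x, y, z]`; voxel `(i, j, k)` (0-based) is centred at
#' continuous coordinate `(i, j, k)` and spans half a voxel to each side, so
#' voxel `k` along z covers `[k - 0.5, k + 0.5)`. All surface heights in the
#' package live in this voxel-center coordinate system.
#'
#' @param data numeric 3D array, axis order (x, y, z).
#' @param spacing positive numeric length-3, physical size of one voxel per
#'   axis (mm, or any consistent unit). Defaults to isotropic 1.
#' @return An object of class `negs_volume`.
#' @export
new_volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (x, y, z)")
  storage.mode(data) <- "double"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers")
  structure(list(data = data, spacing = spacing), class = "negs_volume")
}

#' @export
print.negs_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<negs_volume> %d x %d x %d, spacing (%s), range [%.4g, %.4g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.negs_volume <- function(x) dim(x$data)

stopifnot_volume <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "negs_volume")) stop(sprintf("`%s` must be a negs_volume", arg))
  invisible(x)
}

check_finite <- function(a, what) {
  bad <- !is.finite(a)
  if (any(bad)) {
    first <- arrayInd(which(bad)[1], dim(a)) - 1L
    stop(sprintf("%s contains %d non-finite values; first at (x,y,z) = (%s)",
                 what, sum(bad), paste(first, collapse = ",")))
  }
  invisible(TRUE)
}

# ---- separable filtering ----------------------------------------------------

#' Discrete Gaussian kernel
#'
#' Samples of a Gaussian truncated at radius `max(1, ceiling(4*sigma))`,
#' normalized to unit sum. With the default cost scale sigma = 0.3 voxel the
#' outer taps are ~4e-3 of the center: an intentionally sharp kernel.
#'
#' @param sigma positive standard deviation in voxels.
#' @return numeric vector of odd length.
#' @export
gaussian_kernel <- function(sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Reflect-pad a matrix along rows by r (r < nrow).
reflect_pad_rows <- function(m, r) {
  n <- nrow(m)
  if (r >= n) { # fall back to edge clamping for very short axes
    top <- m[rep(1L, r), , drop = FALSE]
    bot <- m[rep(n, r), , drop = FALSE]
  } else {
    top <- m[(r + 1):2, , drop = FALSE]
    bot <- m[(n - 1):(n - r), , drop = FALSE]
  }
  rbind(top, m, bot)
}

# Convolve a 3D array with a symmetric 1D kernel along one axis, reflect
# boundary. Works by permuting the target axis first and filtering the
# columns of the flattened matrix in one stats::filter call.
conv_axis <- function(a, kern, axis) {
  d <- dim(a)
  if (length(kern) == 1L) return(a * kern)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  r <- (length(kern) - 1L) %/% 2L
  mp <- reflect_pad_rows(m, r)
  f <- stats::filter(mp, kern, sides = 2)
  out <- matrix(f[(r + 1):(r + dp[1]), ], nrow = dp[1])
  dim(out) <- dp
  aperm(out, order(perm))
}

# Separable Gaussian smoothing of a 3D array; sigmas recycled to length 3.
smooth3 <- function(a, sigma) {
  sigma <- rep_len(sigma, 3L)
  for (ax in 1:3) if (sigma[ax] > 0) a <- conv_axis(a, gaussian_kernel(sigma[ax]), ax)
  a
}

# Central differences along one axis, reflect boundary (so the boundary
# derivative is 0 for the first/last sample pair mirror).
central_diff <- function(a, axis) {
  d <- dim(a)
  n <- d[axis]
  if (n == 1L) return(array(0, d))
  idx_hi <- c(2:n, n - 1L)
  idx_lo <- c(2L, 1:(n - 1L))
  slice <- function(i) {
    switch(axis, a[i, , , drop = FALSE], a[, i, , drop = FALSE], a[, , i, drop = FALSE])
  }
  out <- (slice(idx_hi) - slice(idx_lo)) / 2
  dim(out) <- d
  out
}

# ---- interpolation ----------------------------------------------------------

# Vectorized trilinear interpolation of a 3D array at fractional 0-based
# coordinates; out-of-range positions are clamped to the grid boundary.
interp3 <- function(a, xi, yi, zi) {
  d <- dim(a)
  xi <- pmin(pmax(xi, 0), d[1] - 1)
  yi <- pmin(pmax(yi, 0), d[2] - 1)
  zi <- pmin(pmax(zi, 0), d[3] - 1)
  x0 <- pmin(floor(xi), d[1] - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(yi), d[2] - 2); y0 <- pmax(y0, 0)
  z0 <- pmin(floor(zi), d[3] - 2); z0 <- pmax(z0, 0)
  if (d[1] == 1L) x0 <- rep(0, length(xi))
  if (d[2] == 1L) y0 <- rep(0, length(yi))
  if (d[3] == 1L) z0 <- rep(0, length(zi))
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1); z1 <- pmin(z0 + 1, d[3] - 1)
  at <- function(x, y, z) a[1 + x + d[1] * (y + d[2] * z)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(x0, y0, z0) + fx * at(x1, y0, z0)) +
              fy       * ((1 - fx) * at(x0, y1, z0) + fx * at(x1, y1, z0))) +
  fz       * ((1 - fy) * ((1 - fx) * at(x0, y0, z1) + fx * at(x1, y0, z1)) +
              fy       * ((1 - fx) * at(x0, y1, z1) + fx * at(x1, y1, z1)))
}

# Bilinear interpolation of a matrix at fractional 0-based coordinates,
# clamped at the boundary.
interp2 <- function(m, xi, yi) {
  d <- dim(m)
  a <- array(m, c(d[1], d[2], 1))
  interp3(a, xi, yi, rep(0, length(xi)))
}

# ---- cylindrical unwrapping -------------------------------------------------

#' Cylindrically unwrap a volume around a lateral center
#'
#' Resamples the volume on rays from `center_xy` in every (x, y) slice plane,
#' producing a volume with axes (angle, slice, radius). A closed, roughly
#' cylindrical boundary (e.g. a vessel wall) becomes a terrain-like surface
#' over the (angle, slice) grid, which the graph search can then segment;
#' [rewrap_surface()] maps such a surface back to per-slice contours.
#'
#' @param vol a [new_volume()] object; lateral axes (x, y), slices along z.
#' @param center_xy numeric length-2, 0-based lateral center of the rays.
#' @param n_angles number of equally spaced ray angles in `[0, 2*pi)`.
#' @param max_radius largest sampled radius in voxels; clipped (with a
#'   warning) to the largest radius inside the lateral field of view.
#' @return A `negs_volume` with axes (angle, slice, radius) and radial
#'   spacing 1 voxel.
#' @export
unwrap_cylindrical <- function(vol, center_xy, n_angles = 360L, max_radius = NULL) {
  stopifnot_volume(vol)
  d <- dim(vol$data)
  cx <- center_xy[1]; cy <- center_xy[2]
  if (cx < 0 || cx > d[1] - 1 || cy < 0 || cy > d[2] - 1)
    stop("`center_xy` must lie inside the lateral field of view")
  rmax_fov <- min(cx, d[1] - 1 - cx, cy, d[2] - 1 - cy)
  if (is.null(max_radius)) max_radius <- floor(rmax_fov)
  if (max_radius > rmax_fov) {
    warning(sprintf("max_radius %.4g exceeds the field of view; clipped to %.4g",
                    max_radius, floor(rmax_fov)))
    max_radius <- floor(rmax_fov)
  }
  nr <- as.integer(max_radius) + 1L
  ang <- 2 * pi * (0:(n_angles - 1L)) / n_angles
  rad <- 0:(nr - 1L)
  xi <- cx + outer(cos(ang), rad)          # n_angles x nr
  yi <- cy + outer(sin(ang), rad)
  out <- array(0, c(n_angles, d[3], nr))
  for (k in seq_len(d[3])) {
    v <- interp2(vol$data[, , k], as.vector(xi), as.vector(yi))
    out[, k, ] <- matrix(v, n_angles, nr)
  }
  u <- new_volume(out, c(2 * pi / n_angles, vol$spacing[3], 1))
  attr(u, "unwrap") <- list(center_xy = c(cx, cy), n_angles = n_angles)
  u
}

#' Map an unwrapped surface back to per-slice contours
#'
#' Inverse of the surface geometry of [unwrap_cylindrical()]: a height field
#' `r(angle, slice)` in the unwrapped volume becomes, per slice, a closed
#' polygon in the original (x, y) plane.
#'
#' @param radii matrix `n_angles x n_slices` of radii (the unwrapped surface
#'   heights, in voxels).
#' @param unwrapped the volume returned by [unwrap_cylindrical()] (carries the
#'   center and angle grid).
#' @return A list with one `data.frame(angle, x, y)` per slice.
#' @export
rewrap_surface <- function(radii, unwrapped) {
  info <- attr(unwrapped, "unwrap")
  if (is.null(info)) stop("`unwrapped` must come from unwrap_cylindrical()")
  na <- info$n_angles
  ang <- 2 * pi * (0:(na - 1L)) / na
  lapply(seq_len(ncol(radii)), function(k) {
    data.frame(angle = ang,
               x = info$center_xy[1] + radii[, k] * cos(ang),
               y = info$center_xy[2] + radii[, k] * sin(ang))
  })
}
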