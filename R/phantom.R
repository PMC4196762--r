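#' Specify a synthetic layered-tissue phantom
#'
#' A phantom is a stack of homogeneous layers separated by continuous,
#' strictly ordered boundary surfaces `z_s(x, y)`. Rendering it emulates the
#' acquisition of a continuous intensity function by a voxel grid: every
#' voxel takes the exact volume-fraction-weighted mixture of the layer
#' intensities it straddles (the partial volume effect that carries the
#' subvoxel boundary information), plus optional additive Gaussian noise.
#'
#' Each surface is either a `function(x, y)` of 0-based lateral voxel
#' coordinates returning heights in voxel-center z coordinates, or a
#' parameter list with fields `z0` (base height), `ax`, `ay` (plane slopes),
#' `amp`, `period_x`, `period_y`, `phase` (a sinusoid
#' `amp * sin(2*pi*(x/period_x + y/period_y) + phase)`); omitted fields
#' default to 0 (periods to `Inf`).
#'
#' @param nx,ny,nz positive integer voxel counts.
#' @param surfaces ordered list of surfaces (bottom to top), as above.
#' @param layer_intensities numeric, one per layer (`length(surfaces) + 1`).
#' @param noise_sd nonnegative additive Gaussian noise standard deviation.
#' @param seed integer RNG seed for the noise draw.
#' @param spacing per-axis physical voxel size.
#' @param min_gap required minimum vertical gap between consecutive surfaces
#'   at every column.
#' @return An object of class `negs_phantom_spec`.
#' @export
phantom_spec <- function(nx, ny, nz, surfaces, layer_intensities,
                         noise_sd = 0, seed = 1L, spacing = c(1, 1, 1),
                         min_gap = 0.5) {
  stopifnot(nx >= 1, ny >= 1, nz >= 2, noise_sd >= 0)
  if (!is.list(surfaces) || length(surfaces) < 1L)
    stop("`surfaces` must be a non-empty list")
  if (length(layer_intensities) != length(surfaces) + 1L)
    stop("need one layer intensity per layer: length(surfaces) + 1")
  if (any(!is.finite(layer_intensities))) stop("layer intensities must be finite")
  spec <- structure(list(nx = as.integer(nx), ny = as.integer(ny),
                         nz = as.integer(nz), surfaces = surfaces,
                         layer_intensities = as.numeric(layer_intensities),
                         noise_sd = noise_sd, seed = as.integer(seed),
                         spacing = as.numeric(spacing), min_gap = min_gap),
                    class = "negs_phantom_spec")
  validate_phantom_heights(spec)
  spec
}

eval_surface <- function(s, x, y) {
  if (is.function(s)) return(s(x, y))
  g <- function(f, d) if (is.null(s[[f]])) d else s[[f]]
  g("z0", 0) + g("ax", 0) * x + g("ay", 0) * y +
    g("amp", 0) * sin(2 * pi * (x / g("period_x", Inf) + y / g("period_y", Inf)) +
                        g("phase", 0))
}

# Heights array nx x ny x n_surfaces on the 0-based lateral grid.
phantom_heights <- function(spec) {
  x <- matrix(as.numeric(0:(spec$nx - 1L)), spec$nx, spec$ny)
  y <- matrix(as.numeric(0:(spec$ny - 1L)), spec$nx, spec$ny, byrow = TRUE)
  h <- vapply(spec$surfaces, eval_surface, x, x = x, y = y)
  array(h, c(spec$nx, spec$ny, length(spec$surfaces)))
}

validate_phantom_heights <- function(spec) {
  h <- phantom_heights(spec)
  ns <- dim(h)[3]
  if (any(!is.finite(h))) stop("surface heights must be finite")
  bad <- which(h < 0 | h > spec$nz - 1, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("surface %d out of [0, nz-1] at column (x,y) = (%d,%d)",
                 bad[1, 3], bad[1, 1] - 1L, bad[1, 2] - 1L))
  if (ns > 1) for (s in seq_len(ns - 1)) {
    gap <- h[, , s + 1] - h[, , s]
    if (any(gap < spec$min_gap)) {
      i <- which(gap < spec$min_gap, arr.ind = TRUE)[1, ]
      stop(sprintf("surfaces %d and %d closer than min_gap at column (x,y) = (%d,%d)",
                   s, s + 1, i[1] - 1L, i[2] - 1L))
    }
  }
  invisible(h)
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render a phantom to a volume and its ground truth
#'
#' Voxel `(i, j, k)` spans `[k - 0.5, k + 0.5)` along z. Its value is the
#' exact average of the piecewise-constant layer intensity field over that
#' interval: single-crossing voxels get the analytic two-intensity mixture
#' and multi-crossing voxels the exact stacked fractions. Gaussian noise with
#' sd `spec$noise_sd` is then added under `spec$seed`, so identical specs
#' render bit-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @return `list(volume, ground_truth)`: the rendered [new_volume()] and a
#'   [surface_set()] of mode `"reference"` carrying the continuous heights.
#' @export
render_phantom <- function(spec) {
  h <- validate_phantom_heights(spec)
  ns <- dim(h)[3]
  nz <- spec$nz
  zlo <- array(rep((0:(nz - 1)) - 0.5, each = spec$nx * spec$ny),
               c(spec$nx, spec$ny, nz))
  acc <- array(0, dim(zlo))
  bounds <- c(-Inf, Inf)
  for (l in seq_len(ns + 1L)) {
    lo <- if (l == 1L) array(-Inf, dim(zlo)) else
      array(rep(h[, , l - 1], nz), dim(zlo))
    hi <- if (l == ns + 1L) array(Inf, dim(zlo)) else
      array(rep(h[, , l], nz), dim(zlo))
    frac <- pmax(0, pmin(hi, zlo + 1) - pmax(lo, zlo))
    acc <- acc + frac * spec$layer_intensities[l]
  }
  if (spec$noise_sd > 0)
    acc <- acc + with_seed(spec$seed,
                           array(stats::rnorm(length(acc), 0, spec$noise_sd), dim(acc)))
  list(volume = new_volume(acc, spec$spacing),
       ground_truth = surface_set(h, mode = "reference", spacing = spec$spacing))
}

# ---- downsampling chain -----------------------------------------------------

# Keys bicubic interpolation kernel, a = -0.5.
keys_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# Effective sampling weights of the chain reconstruct -> anti-alias -> sample:
# the value at coarse center x is sum_m w(x - m) I[m] with w = G_sd * keys
# (computed by quadrature on a 1/64 grid), or w = keys without anti-alias.
# `frac` is the constant fractional part of the coarse centers; row offset j
# relative to floor(x) carries weight w(frac - j). Normalized to unit sum.
chain_weights <- function(f, antialias, frac) {
  if (!antialias) {
    R <- 2
    j <- ceiling(frac - R):floor(frac + R)
    w <- keys_kernel(frac - j)
  } else {
    sd <- 0.4 * f
    R <- 2 + 4 * sd
    j <- ceiling(frac - R):floor(frac + R)
    tau <- seq(-4 * sd, 4 * sd, by = 1 / 64)
    g <- exp(-tau^2 / (2 * sd^2))
    g <- g / sum(g)
    w <- vapply(frac - j, function(o) sum(g * keys_kernel(o - tau)), 0)
  }
  list(j = j, w = w / sum(w))
}

downsample_axis <- function(a, f, axis, antialias) {
  d <- dim(a)
  n <- d[axis]
  if (f == 1L && !antialias) return(a)
  nout <- n %/% f
  if (nout * f != n)
    message(sprintf("axis %d length %d not divisible by %d; dropping %d trailing voxels",
                    axis, n, f, n - nout * f))
  centers <- (0:(nout - 1)) * f + (f - 1) / 2
  frac <- centers[1] - floor(centers[1])         # constant across k
  cw <- chain_weights(f, antialias, frac)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  pad <- max(abs(cw$j)) + 1L
  mp <- reflect_pad_rows(m, min(pad, n - 1L))
  npad <- nrow(mp)
  off <- (npad - n) / 2                           # actual pad applied
  base <- floor(centers) + off                    # 1-based row of offset j = 0 is base+1
  out <- matrix(0, nout, ncol(m))
  for (i in seq_along(cw$j)) {
    rows <- pmin(pmax(base + 1L + cw$j[i], 1L), npad)
    out <- out + cw$w[i] * mp[rows, , drop = FALSE]
  }
  dim(out) <- c(nout, dp[2], dp[3])
  aperm(out, order(perm))
}

#' Downsample a volume through the reconstruction chain
#'
#' Emulates acquiring the same scene at lower resolution: a continuous signal
#' is reconstructed from the discrete samples by Keys bicubic interpolation
#' (a = -0.5), low-pass anti-alias filtered (Gaussian, sd `0.4 * factor`
#' voxels per decimated axis), and re-sampled at the coarse rate. Coarse
#' voxel `k` covers fine voxels `[k*f, (k+1)*f)`; its center sits at fine
#' coordinate `k*f + (f-1)/2`. Axis lengths not divisible by their factor
#' drop the trailing remainder (logged).
#'
#' @param vol a [new_volume()].
#' @param factors per-axis positive integer decimation factors.
#' @param antialias apply the anti-alias filter (default `TRUE`).
#' @return The downsampled [new_volume()]; spacing multiplied by `factors`.
#' @export
downsample_volume <- function(vol, factors, antialias = TRUE) {
  stopifnot_volume(vol)
  factors <- as.integer(rep_len(factors, 3L))
  if (any(factors < 1L)) stop("downsampling factors must be >= 1")
  a <- vol$data
  for (ax in 1:3) if (factors[ax] > 1L || antialias)
    a <- downsample_axis(a, factors[ax], ax, antialias && factors[ax] > 1L)
  new_volume(a, vol$spacing * factors)
}

#' Map reference surfaces from a fine grid to a downsampled grid
#'
#' Converts heights defined on the high-resolution grid into the coordinate
#' system of the grid produced by [downsample_volume()] with the same
#' factors: z heights are shifted by the resampling phase offset
#' `(f_z - 1)/2` and divided by `f_z`; lateral positions are re-sampled at
#' the coarse column centers by bilinear interpolation of the height field.
#'
#' @param gt a [surface_set()] on the fine grid.
#' @param factors per-axis positive integer factors (as passed to
#'   [downsample_volume()]).
#' @param offset_convention `"center"` (the package-wide convention: voxel
#'   centers at integer coordinates on both grids) or `"corner"` (zero phase
#'   offset).
#' @return A [surface_set()] on the coarse grid.
#' @export
map_surface_to_grid <- function(gt, factors, offset_convention = c("center", "corner")) {
  offset_convention <- match.arg(offset_convention)
  factors <- as.integer(rep_len(factors, 3L))
  if (any(factors < 1L)) stop("factors must be >= 1")
  h <- gt$heights
  d <- dim(h)
  nxo <- d[1] %/% factors[1]
  nyo <- d[2] %/% factors[2]
  phase <- function(f) if (offset_convention == "center") (f - 1) / 2 else 0
  cx <- (0:(nxo - 1)) * factors[1] + phase(factors[1])
  cy <- (0:(nyo - 1)) * factors[2] + phase(factors[2])
  xi <- matrix(cx, nxo, nyo)
  yi <- matrix(cy, nxo, nyo, byrow = TRUE)
  out <- array(0, c(nxo, nyo, d[3]))
  for (s in seq_len(d[3]))
    out[, , s] <- (interp2(h[, , s], as.vector(xi), as.vector(yi)) - phase(factors[3])) /
      factors[3]
  surface_set(out, mode = gt$mode, spacing = gt$spacing * factors)
}
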