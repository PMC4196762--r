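#' On-surface cost from a Gaussian derivative filter
#'
#' Builds the on-surface cost volume `c = -s * d/dz (G_sigma * I)`: the
#' z-component of the Gaussian-regularized intensity gradient, with sign
#' `s = +1` for a `dark_to_bright` transition (intensity increasing with z)
#' and `s = -1` for `bright_to_dark`, so that the sought transition yields
#' the most negative cost. Lower cost means higher likelihood that the voxel
#' lies on the surface. Smoothing is separable with the same sigma in all
#' three dimensions unless a length-3 sigma is given; convolution uses
#' reflect padding and the z derivative is taken by central differences on
#' the smoothed volume.
#'
#' @param vol a [new_volume()].
#' @param sigma Gaussian scale in voxels (scalar or length 3); the default
#'   0.3 voxel is deliberately sharp so partial-volume gradients are not
#'   washed out.
#' @param transition `"dark_to_bright"` or `"bright_to_dark"`.
#' @return A cost volume: a `negs_cost` object (also a `negs_volume`) with
#'   fields `sigma`, `transition` and `provenance = "raw"`.
#' @export
gaussian_derivative_cost <- function(vol, sigma = 0.3,
                                     transition = c("dark_to_bright", "bright_to_dark")) {
  stopifnot_volume(vol)
  transition <- match.arg(transition)
  sigma <- rep_len(as.numeric(sigma), 3L)
  if (any(sigma <= 0)) stop("`sigma` must be > 0")
  check_finite(vol$data, "intensity volume")
  s <- if (transition == "dark_to_bright") 1 else -1
  g <- central_diff(smooth3(vol$data, sigma), 3L)
  new_cost_volume(-s * g, vol$spacing, sigma, transition, "raw")
}

#' Wrap an arbitrary array as an on-surface cost volume
#'
#' Any cost term can drive the graph search, not only the Gaussian
#' derivative: lower values must mean higher likelihood that the voxel lies
#' on the surface.
#'
#' @param values finite numeric 3D array of costs.
#' @param spacing per-axis voxel size.
#' @param transition transition polarity tag carried along for bookkeeping.
#' @return A `negs_cost` object with `provenance = "raw"`.
#' @export
as_cost_volume <- function(values, spacing = c(1, 1, 1),
                           transition = "dark_to_bright") {
  check_finite(values, "cost volume")
  new_cost_volume(values, as.numeric(spacing), NA_real_, transition, "raw")
}

new_cost_volume <- function(values, spacing, sigma, transition, provenance) {
  v <- new_volume(values, spacing)
  v$sigma <- sigma
  v$transition <- transition
  v$provenance <- provenance
  class(v) <- c("negs_cost", class(v))
  v
}

#' @export
print.negs_cost <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<negs_cost %s> %d x %d x %d, transition %s, sigma (%s), range [%.4g, %.4g]\n",
              x$provenance, d[1], d[2], d[3], x$transition,
              paste(signif(x$sigma, 3), collapse = ", "), min(x$data), max(x$data)))
  invisible(x)
}

#' Warp a cost volume to the deformed node locations
#'
#' After the nodes move to `p + D(p)`, each node must carry the cost at its
#' new location: `c'(p) = c(p + D(p))`, evaluated by trilinear interpolation
#' of the raw cost (sample positions outside the grid are clamped to the
#' boundary). This is what stretches low-cost regions out over several
#' nodes, i.e. raises node density where the surface is likely to pass.
#'
#' @param cost a raw cost volume from [gaussian_derivative_cost()].
#' @param D a normalized [compute_deformation()] field on the same grid
#'   (every displacement component at most half a voxel).
#' @return The warped cost volume, `provenance = "warped"`.
#' @export
warp_costs <- function(cost, D) {
  if (!inherits(cost, "negs_cost")) stop("`cost` must be a negs_cost")
  if (!inherits(D, "negs_deformation")) stop("`D` must be a negs_deformation")
  d <- dim(cost$data)
  if (!identical(d, dim(D$dz))) stop("`cost` and `D` must share one grid")
  lim <- 0.5 * cost$spacing + 1e-9
  if (max(abs(D$dx)) > lim[1] || max(abs(D$dy)) > lim[2] || max(abs(D$dz)) > lim[3])
    stop("deformation field is not normalized: displacement exceeds half a voxel")
  if (all(D$dx == 0) && all(D$dy == 0) && all(D$dz == 0)) {
    out <- cost$data                      # bit-exact identity for D == 0
  } else {
    xi <- array(rep(0:(d[1] - 1), times = d[2] * d[3]), d) + D$dx / cost$spacing[1]
    yi <- array(rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]), d) + D$dy / cost$spacing[2]
    zi <- array(rep(0:(d[3] - 1), each = d[1] * d[2]), d) + D$dz / cost$spacing[3]
    out <- array(interp3(cost$data, xi, yi, zi), d)
  }
  new_cost_volume(out, cost$spacing, cost$sigma, cost$transition, "warped")
}
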