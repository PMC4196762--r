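#' Deformation field from the negative cost gradient
#'
#' Computes the un-normalized node deformation field
#' `D = -grad(G_sigma_reg * c)`: the negative gradient of the
#' Gaussian-regularized cost, by central differences with reflect boundary.
#' Vectors point from each voxel center toward locally decreasing cost, i.e.
#' toward the likely boundary, so that after normalization and application
#' the node density rises where the surface is expected. Displacements are
#' stored in physical units per axis (gradients are taken with respect to
#' physical coordinates).
#'
#' @param cost a cost volume from [gaussian_derivative_cost()].
#' @param sigma_reg regularization scale in voxels (0 disables smoothing);
#'   larger values trade localization accuracy for capture range.
#' @return A `negs_deformation` object with component arrays `dx`, `dy`,
#'   `dz`, the grid `spacing`, `eta = NA` (not yet normalized), `sigma_reg`
#'   and `method = "neg_gradient"`.
#' @export
compute_deformation <- function(cost, sigma_reg = 0.3) {
  if (!inherits(cost, "negs_cost")) stop("`cost` must be a negs_cost")
  if (!is.finite(sigma_reg) || sigma_reg < 0) stop("`sigma_reg` must be >= 0")
  check_finite(cost$data, "cost volume")
  # gradients per voxel step: displacements are voxel-relative before the
  # physical scaling, so anisotropic spacing does not distort eta
  sm <- if (sigma_reg > 0) smooth3(cost$data, sigma_reg) else cost$data
  new_deformation(dx = -central_diff(sm, 1L) * cost$spacing[1],
                  dy = -central_diff(sm, 2L) * cost$spacing[2],
                  dz = -central_diff(sm, 3L) * cost$spacing[3],
                  spacing = cost$spacing, eta = NA_real_,
                  sigma_reg = sigma_reg, method = "neg_gradient")
}

new_deformation <- function(dx, dy, dz, spacing, eta, sigma_reg, method) {
  structure(list(dx = dx, dy = dy, dz = dz, spacing = spacing,
                 eta = eta, sigma_reg = sigma_reg, method = method),
            class = "negs_deformation")
}

#' @export
print.negs_deformation <- function(x, ...) {
  d <- dim(x$dz)
  cat(sprintf("<negs_deformation %s> %d x %d x %d, eta = %s, max |D|/spacing = %.4g\n",
              x$method, d[1], d[2], d[3], format(x$eta),
              max(abs(x$dx) / x$spacing[1], abs(x$dy) / x$spacing[2],
                  abs(x$dz) / x$spacing[3])))
  invisible(x)
}

#' Zero deformation field on a grid
#'
#' Convenience constructor for the conventional (undeformed) pipeline and
#' for tests.
#'
#' @param dims integer length-3 grid dimensions.
#' @param spacing per-axis voxel size.
#' @return A normalized-by-convention zero `negs_deformation` (`eta = 1`).
#' @export
zero_deformation <- function(dims, spacing = c(1, 1, 1)) {
  z <- array(0, dims)
  new_deformation(z, z, z, as.numeric(spacing), eta = 1,
                  sigma_reg = 0, method = "neg_gradient")
}

#' Normalize a deformation field to half-voxel maximum displacement
#'
#' The worst-case quantization error of a voxel grid is half the voxel size,
#' so the field is scaled by one global factor
#' `eta = 0.5 / max over voxels and axes of |D_a| / spacing_a`,
#' making the largest per-axis relative displacement exactly half a voxel
#' while preserving all relative magnitudes. An identically zero field is
#' returned unchanged with `eta = 1`. A per-component safety clamp to
#' `+-0.5 * spacing_a` guards against floating-point overshoot.
#'
#' @param D a `negs_deformation`.
#' @param spacing optional spacing override (defaults to the field's own).
#' @return The normalized field, with `eta` set to the applied factor.
#' @export
normalize_deformation <- function(D, spacing = D$spacing) {
  if (!inherits(D, "negs_deformation")) stop("`D` must be a negs_deformation")
  for (cmp in c("dx", "dy", "dz")) check_finite(D[[cmp]], cmp)
  mx <- max(abs(D$dx) / spacing[1], abs(D$dy) / spacing[2], abs(D$dz) / spacing[3])
  eta <- if (mx == 0) 1 else 0.5 / mx
  out <- D
  out$dx <- pmin(pmax(D$dx * eta, -0.5 * spacing[1]), 0.5 * spacing[1])
  out$dy <- pmin(pmax(D$dy * eta, -0.5 * spacing[2]), 0.5 * spacing[2])
  out$dz <- pmin(pmax(D$dz * eta, -0.5 * spacing[3]), 0.5 * spacing[3])
  out$eta <- eta
  out
}

#' Gradient vector flow deformation field
#'
#' Alternative to [compute_deformation()] with a larger capture range: the
#' field `v` minimizing `integral mu * |grad v|^2 + |grad f|^2 * |v - grad f|^2`
#' with `f = G_sigma_reg * (-c)`, i.e. a feature-preserving diffusion of the
#' gradient of the (negated, smoothed) cost. Solved by explicit-Euler
#' diffusion iterations with a stable step size until the largest update
#' falls below `tol` or `n_iter` is reached.
#'
#' @param cost a cost volume.
#' @param mu smoothness weight (> 0); larger values diffuse farther.
#' @param n_iter maximum number of iterations.
#' @param tol convergence threshold on the maximum component update.
#' @param sigma_reg Gaussian scale for `f`.
#' @return An un-normalized `negs_deformation` with `method = "gvf"`; pass it
#'   through [normalize_deformation()] before use.
#' @export
gvf_deformation <- function(cost, mu = 0.1, n_iter = 200L, tol = 1e-4,
                            sigma_reg = 0.3) {
  if (!inherits(cost, "negs_cost")) stop("`cost` must be a negs_cost")
  if (mu <= 0) stop("`mu` must be > 0")
  if (n_iter < 1L) stop("`n_iter` must be >= 1")
  f <- smooth3(-cost$data, sigma_reg)
  sp <- cost$spacing
  gx <- central_diff(f, 1L)   # per voxel step, as in compute_deformation
  gy <- central_diff(f, 2L)
  gz <- central_diff(f, 3L)
  g2 <- gx^2 + gy^2 + gz^2
  dt <- 0.9 / (6 * mu + max(g2) + 1e-12)
  lap <- function(a) {
    d <- dim(a)
    out <- array(0, d)
    for (ax in 1:3) {
      n <- d[ax]
      if (n == 1L) next
      hi <- c(2:n, n - 1L); lo <- c(2L, 1:(n - 1L))
      out <- out - 2 * a + switch(ax,
                          a[hi, , , drop = FALSE] + a[lo, , , drop = FALSE],
                          a[, hi, , drop = FALSE] + a[, lo, , drop = FALSE],
                          a[, , hi, drop = FALSE] + a[, , lo, drop = FALSE])
    }
    out
  }
  vx <- gx; vy <- gy; vz <- gz
  for (it in seq_len(n_iter)) {
    ux <- dt * (mu * lap(vx) - g2 * (vx - gx))
    uy <- dt * (mu * lap(vy) - g2 * (vy - gy))
    uz <- dt * (mu * lap(vz) - g2 * (vz - gz))
    vx <- vx + ux; vy <- vy + uy; vz <- vz + uz
    if (any(!is.finite(vx)) || any(!is.finite(vy)) || any(!is.finite(vz)))
      stop(sprintf("GVF iteration diverged at step %d", it))
    if (max(abs(ux), abs(uy), abs(uz)) < tol) break
  }
  new_deformation(vx * sp[1], vy * sp[2], vz * sp[3], sp, eta = NA_real_,
                  sigma_reg = sigma_reg, method = "gvf")
}

#' Apply a deformation field to the voxel-center node positions
#'
#' Moves every node from its voxel center `p` to `p + D(p)`. Because a
#' normalized field displaces by strictly less than the inter-node distance,
#' the deformed z positions along every column remain strictly increasing,
#' which is what lets the intra-column graph arcs stay unchanged; this is
#' asserted.
#'
#' @param D a normalized `negs_deformation`.
#' @return A list of arrays `x`, `y`, `z` of deformed positions in voxel
#'   index coordinates (position divided by spacing), each shaped like the
#'   grid; `z` is the `zprime` used for graph construction.
#' @export
apply_deformation <- function(D) {
  if (!inherits(D, "negs_deformation")) stop("`D` must be a negs_deformation")
  d <- dim(D$dz)
  x <- array(rep(0:(d[1] - 1), times = d[2] * d[3]), d) + D$dx / D$spacing[1]
  y <- array(rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]), d) + D$dy / D$spacing[2]
  z <- array(rep(0:(d[3] - 1), each = d[1] * d[2]), d) + D$dz / D$spacing[3]
  if (d[3] > 1) {
    gaps <- z[, , 2:d[3], drop = FALSE] - z[, , 1:(d[3] - 1), drop = FALSE]
    if (any(gaps <= 0))
      stop("deformed column order violated; is the field normalized?")
  }
  list(x = x, y = y, z = z)
}

#' Write a deformation field as three scalar volumes
#'
#' @param D a `negs_deformation`.
#' @param prefix output path prefix; files `<prefix>_dx.<ext>` etc. are
#'   written.
#' @param ext volume format extension (see [write_volume()]).
#' @return The three paths, invisibly.
#' @export
write_deformation <- function(D, prefix, ext = "nrrd") {
  paths <- sprintf("%s_%s.%s", prefix, c("dx", "dy", "dz"), ext)
  for (i in 1:3)
    write_volume(new_volume(D[[c("dx", "dy", "dz")[i]]], D$spacing), paths[i])
  invisible(paths)
}
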