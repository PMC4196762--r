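# Shared fixtures and independent oracles, all built in code.

# Random admissible deformation field: uniform components, normalized so the
# largest relative displacement is exactly half a voxel.
random_deformation <- function(dims, seed, spacing = c(1, 1, 1)) {
  set.seed(seed)
  D <- zero_deformation(dims, spacing)
  D$dx <- array(stats::runif(prod(dims), -1, 1), dims) * spacing[1]
  D$dy <- array(stats::runif(prod(dims), -1, 1), dims) * spacing[2]
  D$dz <- array(stats::runif(prod(dims), -1, 1), dims) * spacing[3]
  normalize_deformation(D)
}

# Random small segmentation graph (uniform costs in [-1, 1]), optionally in
# deformed coordinates.
random_small_graph <- function(seed, lambda = 1L, dims = c(2L, 2L, 4L),
                               deformed = TRUE, sep = c(1, 3)) {
  set.seed(seed)
  costs <- lapply(seq_len(lambda), function(s)
    as_cost_volume(array(stats::runif(prod(dims), -1, 1), dims)))
  D <- if (deformed) random_deformation(dims, seed + 7919L) else NULL
  cons <- surface_constraints(lambda, dx = 1, dy = 1,
                              sep = if (lambda > 1L) sep else NULL)
  if (!is.null(D)) costs <- lapply(costs, warp_costs, D = D)
  suppressMessages(build_graph(costs, D = D, cons = cons))
}

# Dense (non-separable, non-FFT) oracle for the Gaussian-derivative cost:
# explicit kernel sums with reflect indexing, then central z differences.
reflect_index <- function(i, n) {
  # 0-based reflect-without-repeat (abcb|abcb...) matching reflect padding
  if (n == 1L) return(rep(0L, length(i)))
  p <- 2L * (n - 1L)
  i <- ((i %% p) + p) %% p
  ifelse(i >= n, p - i, i)
}

dense_gaussian_derivative <- function(a, sigma, sign) {
  d <- dim(a)
  kx <- gaussian_kernel(sigma[1]); ky <- gaussian_kernel(sigma[2])
  kz <- gaussian_kernel(sigma[3])
  rx <- (length(kx) - 1) / 2; ry <- (length(ky) - 1) / 2; rz <- (length(kz) - 1) / 2
  sm <- array(0, d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    acc <- 0
    for (i in -rx:rx) for (j in -ry:ry) for (k in -rz:rz) {
      xi <- reflect_index(x - 1 + i, d[1]) + 1
      yi <- reflect_index(y - 1 + j, d[2]) + 1
      zi <- reflect_index(z - 1 + k, d[3]) + 1
      acc <- acc + kx[i + rx + 1] * ky[j + ry + 1] * kz[k + rz + 1] * a[xi, yi, zi]
    }
    sm[x, y, z] <- acc
  }
  g <- array(0, d)
  for (z in 1:d[3]) {
    zh <- if (z == d[3]) d[3] - 1 else z + 1
    zl <- if (z == 1) 2 else z - 1
    g[, , z] <- (sm[, , zh] - sm[, , zl]) / 2
  }
  -sign * g
}

# Supersampled rendering oracle: midpoint-rule average of the layer field
# over each voxel's z extent.
supersampled_voxel_values <- function(spec, nsub = 1000L) {
  h <- negseg:::phantom_heights(spec)
  out <- array(0, c(spec$nx, spec$ny, spec$nz))
  sub <- (seq_len(nsub) - 0.5) / nsub
  for (x in 1:spec$nx) for (y in 1:spec$ny) {
    hs <- h[x, y, ]
    for (k in 1:spec$nz) {
      zs <- (k - 1) - 0.5 + sub
      layer <- findInterval(zs, hs) + 1L
      out[x, y, k] <- mean(spec$layer_intensities[layer])
    }
  }
  out
}

# Flat-surface step phantom at height `h` used by several tests.
step_phantom <- function(h, nx = 8L, ny = 6L, nz = 16L, noise_sd = 0, seed = 1L,
                         intensities = c(0.05, 0.85)) {
  phantom_spec(nx, ny, nz, surfaces = list(list(z0 = h)),
               layer_intensities = intensities, noise_sd = noise_sd, seed = seed)
}

# Segment one rendered phantom volume in a given mode with default OCT
# settings; returns the surface_set.
segment_mode <- function(vol, mode, lambda = 1L, sep = c(3, 8)) {
  cfg <- run_config(mode = mode, lambda = lambda,
                    sep = if (lambda > 1L) sep else c(3, 8))
  suppressMessages(segment_volume(vol, cfg))
}
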