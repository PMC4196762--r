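test_that("partial-volume rendering is exact for flat boundaries", {
  # boundary on a voxel edge (half-integer in center coordinates): no mixing
  sp <- step_phantom(2.5, nx = 3, ny = 2, nz = 6, intensities = c(0, 1))
  v <- render_phantom(sp)$volume$data
  expect_identical(unique(as.vector(v[, , 1:3])), 0)
  expect_identical(unique(as.vector(v[, , 4:6])), 1)

  # single-crossing voxel gets the analytic mixture: boundary at 1.8 cuts
  # voxel 2 ([1.5, 2.5)) into 0.3 below / 0.7 above
  sp <- step_phantom(1.8, nx = 2, ny = 2, nz = 5, intensities = c(0, 1))
  v <- render_phantom(sp)$volume$data
  expect_equal(v[1, 1, ], c(0, 0, 0.7, 1, 1), tolerance = 1e-12)

  # multi-crossing voxel: two surfaces inside one voxel stack their fractions
  sp <- phantom_spec(1, 1, 5, surfaces = list(list(z0 = 1.7), list(z0 = 2.3)),
                     layer_intensities = c(0, 1, 0), min_gap = 0.5)
  v <- render_phantom(sp)$volume$data
  expect_equal(v[1, 1, 3], 0.6, tolerance = 1e-12)  # only [1.7, 2.3) is bright
})

test_that("rendered voxels match a supersampled integration oracle", {
  sp <- phantom_spec(6, 4, 12,
                     surfaces = list(list(z0 = 4.3, amp = 1.7, period_x = 6,
                                          period_y = 8, phase = 0.71),
                                     list(z0 = 8.2, amp = 0.9, period_x = 5,
                                          phase = 2.2)),
                     layer_intensities = c(0.1, 0.6, 0.9))
  v <- render_phantom(sp)$volume$data
  expect_equal(v, supersampled_voxel_values(sp), tolerance = 1e-3)
})

test_that("noise-free mean intensity conserves the analytic volume fractions", {
  sp <- phantom_spec(5, 5, 10, surfaces = list(list(z0 = 3.21, ax = 0.11)),
                     layer_intensities = c(0.2, 0.8))
  r <- render_phantom(sp)
  # fraction of each column below the surface: (h + 0.5) / nz
  frac <- (r$ground_truth$heights[, , 1] + 0.5) / sp$nz
  expected <- mean(frac * 0.2 + (1 - frac) * 0.8)
  expect_equal(mean(r$volume$data), expected, tolerance = 1e-9)
})

test_that("rendering is deterministic and validation names offending columns", {
  sp <- phantom_spec(4, 3, 8, surfaces = list(list(z0 = 3.3)),
                     layer_intensities = c(0, 1), noise_sd = 0.1, seed = 42L)
  expect_identical(render_phantom(sp)$volume$data, render_phantom(sp)$volume$data)

  expect_error(phantom_spec(4, 3, 8,
                            surfaces = list(list(z0 = 5), list(z0 = 3)),
                            layer_intensities = c(0, 0.5, 1)),
               "closer than min_gap")
  expect_error(phantom_spec(4, 3, 8, surfaces = list(list(z0 = 9.5)),
                            layer_intensities = c(0, 1)),
               "out of \\[0, nz-1\\]")
})

test_that("downsampling chain: identity, constants and linear reproduction", {
  set.seed(5)
  v <- new_volume(array(runif(4 * 3 * 8), c(4, 3, 8)))
  expect_identical(downsample_volume(v, c(1, 1, 1), antialias = FALSE)$data, v$data)

  const <- new_volume(array(3.7, c(8, 6, 20)))
  dsc <- downsample_volume(const, c(2, 3, 10))
  expect_equal(dim(dsc$data), c(4L, 2L, 2L))
  expect_equal(as.vector(dsc$data), rep(3.7, 16), tolerance = 1e-12)
  expect_equal(dsc$spacing, c(2, 3, 10))

  # 1D ramp through the full chain: the antialiased Keys reconstruction of a
  # linear signal is the same linear signal, so coarse samples must sit on
  # the ramp at the coarse center positions k*f + (f-1)/2
  n <- 200L; f <- 10L
  ramp <- new_volume(array(0.25 + 0.5 * (0:(n - 1)), c(1, 1, n)))
  ds <- downsample_volume(ramp, c(1, 1, f))
  k <- 0:(n %/% f - 1)
  expected <- 0.25 + 0.5 * (k * f + (f - 1) / 2)
  interior <- 4:17  # footprint of the kernel fully inside the signal
  expect_equal(ds$data[1, 1, interior], expected[interior], tolerance = 1e-6)
})

test_that("downsampling a grid-aligned step keeps the crossing within half a coarse voxel", {
  sp <- step_phantom(99.5, nx = 2, ny = 2, nz = 200, intensities = c(0, 1))
  v <- render_phantom(sp)$volume
  ds <- downsample_volume(v, c(1, 1, 10))
  prof <- ds$data[1, 1, ]
  ix <- max(which(prof < 0.5))
  crossing <- (ix - 1) + (0.5 - prof[ix]) / (prof[ix + 1] - prof[ix])
  expect_lt(abs(crossing - (99.5 - 4.5) / 10), 0.5)
})

test_that("surface mapping to the coarse grid follows the phase convention", {
  h <- array(23.0, c(20, 10, 1))
  gt <- surface_set(h)
  expect_identical(map_surface_to_grid(gt, c(1, 1, 1))$heights, gt$heights)

  m <- map_surface_to_grid(gt, c(1, 1, 10))
  expect_equal(unique(as.vector(m$heights)), (23.0 - 4.5) / 10, tolerance = 1e-12)

  # affine invariance: a tilted plane maps to a plane
  x <- matrix(0:19, 20, 10); y <- matrix(0:9, 20, 10, byrow = TRUE)
  plane <- surface_set(array(40 + 1.5 * x - 0.8 * y, c(20, 10, 1)))
  mp <- map_surface_to_grid(plane, c(2, 2, 10))$heights[, , 1]
  cx <- (0:9) * 2 + 0.5; cy <- (0:4) * 2 + 0.5
  expected <- (40 + 1.5 * outer(cx, rep(1, 5)) - 0.8 * outer(rep(1, 10), cy) - 4.5) / 10
  expect_equal(mp, expected, tolerance = 1e-12)
})

test_that("mapped step-phantom height agrees with the downsampled edge response", {
  sp <- step_phantom(23.0, nx = 2, ny = 2, nz = 60, intensities = c(0, 1))
  r <- render_phantom(sp)
  ds <- downsample_volume(r$volume, c(1, 1, 10))
  mapped <- map_surface_to_grid(r$ground_truth, c(1, 1, 10))$heights[1, 1, 1]
  expect_equal(mapped, 1.85, tolerance = 1e-12)
  # subvoxel 50%-crossing of the (symmetric) coarse edge response
  prof <- ds$data[1, 1, ]
  mid <- (min(prof) + max(prof)) / 2
  i <- max(which(prof < mid))
  crossing <- (i - 1) + (mid - prof[i]) / (prof[i + 1] - prof[i])
  expect_lt(abs(crossing - mapped), 0.1)
})

test_that("cylindrical unwrap and rewrap recover circular boundaries", {
  # antialiased disk: linear ramp of width 2 at the boundary radius, so the
  # 50% level sits exactly on the circle even under bilinear sampling
  nx <- 41L; ny <- 41L; cx <- 20; cy <- 20; R <- 12
  mk_disk <- function(cx0) {
    x <- matrix(0:(nx - 1), nx, ny); y <- matrix(0:(ny - 1), nx, ny, byrow = TRUE)
    d <- sqrt((x - cx0)^2 + (y - cy)^2)
    arr <- array(pmin(pmax(0.5 + (d - R) / 2, 0), 1), c(nx, ny, 2))  # dark inside
    new_volume(arr)
  }
  u <- unwrap_cylindrical(mk_disk(cx), c(cx, cy), n_angles = 90)
  prof <- u$data[, 1, ]
  crossing <- apply(prof, 1, function(p) {
    i <- max(which(p < 0.5)); (i - 1) + (0.5 - p[i]) / (p[i + 1] - p[i])
  })
  expect_lt(max(abs(crossing - R)), 0.1)

  contours <- rewrap_surface(matrix(crossing, 90, 2), u)
  dev <- sqrt((contours[[1]]$x - cx)^2 + (contours[[1]]$y - cy)^2) - R
  expect_lt(max(abs(dev)), 0.5)

  # off-center circle: unwrapped boundary equals the polar radius equation
  d0 <- 3
  u2 <- unwrap_cylindrical(mk_disk(cx + d0), c(cx, cy), n_angles = 90)
  prof2 <- u2$data[, 1, ]
  crossing2 <- apply(prof2, 1, function(p) {
    i <- max(which(p < 0.5)); (i - 1) + (0.5 - p[i]) / (p[i + 1] - p[i])
  })
  ang <- 2 * pi * (0:89) / 90
  polar <- d0 * cos(ang) + sqrt(R^2 - d0^2 * sin(ang)^2)
  expect_lt(max(abs(crossing2 - polar)), 0.1)

  expect_warning(unwrap_cylindrical(mk_disk(cx), c(cx, cy), 36, max_radius = 100),
                 "clipped")
})
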