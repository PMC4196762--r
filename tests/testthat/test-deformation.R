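test_that("uniform cost yields a zero field; mirrored cost negates dz", {
  flat <- as_cost_volume(array(1.5, c(3, 3, 8)))
  D <- compute_deformation(flat)
  expect_identical(unique(c(D$dx, D$dy, D$dz)), 0)

  set.seed(21)
  a <- array(runif(4 * 3 * 10), c(4, 3, 10))
  D1 <- compute_deformation(as_cost_volume(a))
  D2 <- compute_deformation(as_cost_volume(a[, , 10:1]))
  expect_equal(D1$dz, -D2$dz[, , 10:1], tolerance = 1e-9)
})

test_that("a quadratic cost valley pulls nodes toward its continuous minimum", {
  z <- 0:15
  cost <- as_cost_volume(array(rep((z - 5.3)^2, each = 1), c(1, 1, 16)))
  D <- compute_deformation(cost, sigma_reg = 0.3)
  dz <- D$dz[1, 1, ]
  interior <- z >= 1 & z <= 14   # reflect boundary pins the end gradients to 0
  expect_true(all(dz[interior & z < 5.3] > 0) && all(dz[interior & z > 5.5] < 0))
  # dense-sampling oracle: argmin of the smoothed cost along z
  sm <- negseg:::smooth3(cost$data, 0.3)[1, 1, ]
  zs <- seq(1, 14, by = 0.001)
  oracle_min <- zs[which.min(stats::spline(z, sm, xout = zs)$y)]
  i <- max(which(dz > 0))
  crossing <- (i - 1) + dz[i] / (dz[i] - dz[i + 1])
  expect_lt(abs(crossing - oracle_min), 0.05)
  expect_lt(abs(crossing - 5.3), 0.05)
})

test_that("normalization scales the maximum relative displacement to exactly half", {
  d <- c(3, 3, 5)
  D <- zero_deformation(d)
  expect_identical(normalize_deformation(D)$eta, 1)

  D$dz[2, 2, 3] <- 2.0
  D$dx[1, 1, 1] <- 0.4
  Dn <- normalize_deformation(D)
  expect_equal(Dn$eta, 0.25, tolerance = 1e-15)
  expect_equal(max(abs(Dn$dz)), 0.5, tolerance = 1e-15)
  expect_equal(max(abs(Dn$dx)), 0.1, tolerance = 1e-15)

  # anisotropic spacing: the largest displacement *relative to its axis
  # spacing* governs the global factor
  Da <- zero_deformation(d, spacing = c(1, 1, 4))
  Da$dz[1, 1, 2] <- 2.0   # relatively 0.5 voxel
  Da$dx[3, 3, 5] <- 0.9   # relatively 0.9 voxel -> governs
  Dan <- normalize_deformation(Da)
  expect_equal(Dan$eta, 0.5 / 0.9, tolerance = 1e-15)
  mx <- max(abs(Dan$dx) / 1, abs(Dan$dy) / 1, abs(Dan$dz) / 4)
  expect_equal(mx, 0.5, tolerance = 1e-12)
})

test_that("GVF limits: zero data field stays zero, strong data term tracks the gradient", {
  flat <- as_cost_volume(array(2, c(4, 4, 8)))
  Dg <- gvf_deformation(flat, mu = 0.1, n_iter = 50)
  expect_identical(unique(c(Dg$dx, Dg$dy, Dg$dz)), 0)

  sp <- step_phantom(7.5, nx = 4, ny = 4, nz = 16, intensities = c(0, 10))
  cost <- gaussian_derivative_cost(render_phantom(sp)$volume)
  Dg <- gvf_deformation(cost, mu = 1e-4, n_iter = 400, tol = 1e-9)
  f <- negseg:::smooth3(-cost$data, 0.3)
  gz <- negseg:::central_diff(f, 3L)
  edge <- which(abs(gz) > 0.5 * max(abs(gz)))
  expect_lt(max(abs(Dg$dz[edge] - gz[edge]) / abs(gz[edge])), 0.05)
})

test_that("GVF extends the capture range beyond the plain negative gradient", {
  z <- 0:39
  prof <- -exp(-((z - 20) / 1.2)^2)   # one narrow cost valley
  cost <- as_cost_volume(array(rep(prof, each = 1), c(1, 1, 40)))
  Dn <- compute_deformation(cost, sigma_reg = 0.3)
  Dg <- gvf_deformation(cost, mu = 0.1, n_iter = 2000, tol = 1e-8)
  reach <- function(dz) {
    nz <- which(abs(dz[1, 1, ]) > 1e-3 * max(abs(dz)))
    max(abs(nz - 1 - 20))
  }
  expect_gte(reach(Dg$dz), 2 * reach(Dn$dz))
})

test_that("deformed node positions keep strict column order", {
  D <- zero_deformation(c(1, 1, 3))
  p <- apply_deformation(D)
  expect_identical(p$z[1, 1, ], c(0, 1, 2))

  D$dz[1, 1, ] <- c(0.4, -0.4, 0.3)
  p <- apply_deformation(D)
  expect_equal(p$z[1, 1, ], c(0.4, 0.6, 2.3), tolerance = 1e-15)

  for (seed in 1:200) {
    Dr <- random_deformation(c(3, 2, 6), seed)
    z <- apply_deformation(Dr)$z
    expect_gt(min(z[, , 2:6] - z[, , 1:5]), 0)
  }
})

test_that("a clean step edge deforms the nearest node onto the boundary", {
  for (phi in c(0.2, 0.5, 0.8)) {
    sp <- step_phantom(7 + phi, nx = 3, ny = 3, nz = 16)
    cost <- gaussian_derivative_cost(render_phantom(sp)$volume)
    D <- normalize_deformation(compute_deformation(cost))
    z <- apply_deformation(D)$z[2, 2, ]
    expect_lt(min(abs(z - (7 + phi))), 0.1)
  }
})
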