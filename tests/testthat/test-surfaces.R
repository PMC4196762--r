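test_that("extraction returns integer heights conventionally, subvoxel when deformed", {
  # base-only closed set: heights are the bottom nodes' z'
  d <- c(3, 2, 4)
  g <- build_graph(as_cost_volume(array(rep(1:4, each = 6), d)))
  s <- extract_surfaces(min_closed_set(g), g)
  expect_identical(unique(as.vector(s$heights)), 0)
  expect_identical(s$mode, "conventional")

  # step phantom with boundary at 4.3: conventional quantizes, deformed lands
  # within 0.1 voxel of the continuous boundary
  sp <- step_phantom(4.3, nx = 6, ny = 4, nz = 12)
  vol <- render_phantom(sp)$volume
  conv <- segment_mode(vol, "conventional")$surfaces
  ne <- segment_mode(vol, "non_euclidean")$surfaces
  expect_true(all(conv$heights %in% c(4, 5)))
  expect_lt(max(abs(ne$heights - 4.3)), 0.1)
  expect_identical(ne$mode, "non_euclidean")
  # node confinement: every height within half a voxel of some node center
  expect_lt(max(abs(ne$heights - round(ne$heights))), 0.5 + 1e-12)
})

test_that("surface resampling reproduces planes exactly and bounds sinusoid error", {
  x <- matrix(0:11, 12, 8); y <- matrix(0:7, 12, 8, byrow = TRUE)
  plane <- surface_set(array(3 + 0.25 * x + 0.5 * y, c(12, 8, 1)))
  same <- resample_surface(plane, c(12, 8))
  expect_equal(same$heights, plane$heights, tolerance = 1e-12)

  half <- resample_surface(plane, c(6, 4))
  cx <- (0:5) * 2 + 0.5; cy <- (0:3) * 2 + 0.5
  expect_equal(half$heights[, , 1],
               3 + 0.25 * outer(cx, rep(1, 4)) + 0.5 * outer(rep(1, 6), cy),
               tolerance = 1e-12)

  sine <- surface_set(array(5 + sin(2 * pi * x / 12), c(12, 8, 1)))
  # doubling the density puts the outermost target centers a quarter voxel
  # outside the source extent; they are clamped (warned) and not asserted on
  up <- suppressWarnings(resample_surface(sine, c(24, 16)))
  back <- resample_surface(up, c(12, 8))
  h2 <- 1  # source grid step
  bound <- h2^2 / 8 * max(abs((2 * pi / 12)^2))  # h^2/8 * max|f''|
  inner <- 2:11
  expect_lt(max(abs(back$heights[inner, , 1] - sine$heights[inner, , 1])), bound)
})

test_that("thickness maps subtract surfaces and respect masks", {
  h <- array(0, c(2, 2, 2))
  h[, , 1] <- 2.25; h[, , 2] <- 7.5
  s <- surface_set(h)
  tm <- thickness_map(s)
  expect_identical(unique(as.vector(tm$values)), 5.25)

  tm0 <- thickness_map(surface_set(array(rep(h[, , 1], 2), c(2, 2, 2))))
  expect_identical(unique(as.vector(tm0$values)), 0)

  mask <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_identical(sum(is.na(thickness_map(s, mask = mask)$values)), 1L)

  bad <- surface_set(array(c(rep(5, 4), rep(1, 4)), c(2, 2, 2)))
  expect_error(thickness_map(bad), "negative thickness")
})

test_that("lateral smoothing preserves planes and conserves impulse mass", {
  x <- matrix(0:19, 20, 15); y <- matrix(0:14, 20, 15, byrow = TRUE)
  plane <- surface_set(array(4 + 0.2 * x - 0.1 * y, c(20, 15, 1)))
  sm <- smooth_surface(plane, fwhm = 2.355)
  expect_identical(sm$mode, "smoothed_conventional")
  # exact linearity holds where the kernel footprint avoids the reflected rim
  expect_equal(sm$heights[6:15, 6:10, 1], plane$heights[6:15, 6:10, 1],
               tolerance = 1e-12)

  imp <- array(0, c(15, 15, 1)); imp[8, 8, 1] <- 1
  smi <- smooth_surface(surface_set(imp), fwhm = 2.355)
  expect_equal(sum(smi$heights), 1, tolerance = 1e-6)
  expect_lt(max(smi$heights), 1)
})

test_that("smoothing a quantized ramp helps, but less than subvoxel search", {
  # staircase of a gentle ramp: smoothing reduces the error against the
  # continuous ramp, but stays above the non-Euclidean result on the same data
  sp <- phantom_spec(24, 8, 14, surfaces = list(list(z0 = 5.1, ax = 0.13)),
                     layer_intensities = c(0.05, 0.85))
  r <- render_phantom(sp)
  conv <- segment_mode(r$volume, "conventional")$surfaces
  sm <- smooth_surface(conv, fwhm = 2.355)
  ne <- segment_mode(r$volume, "non_euclidean")$surfaces
  err <- function(s) mean(abs(s$heights - r$ground_truth$heights))
  expect_lt(err(sm), err(conv))
  expect_lt(err(ne), err(sm))
})

test_that("surface TSV round-trips heights, mode and missing values", {
  set.seed(51)
  h <- array(runif(5 * 4 * 2, 0, 10), c(5, 4, 2))
  s <- surface_set(h, mode = "non_euclidean")
  path <- tempfile(fileext = ".tsv")
  write_surfaces(s, path)
  s2 <- read_surfaces(path)
  expect_equal(s2$heights, h, tolerance = 1e-12)
  expect_identical(s2$mode, "non_euclidean")

  h[2, 2, 1] <- NA
  write_surfaces(surface_set(h), path)
  expect_identical(is.na(read_surfaces(path)$heights[2, 2, 1]), TRUE)
})
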