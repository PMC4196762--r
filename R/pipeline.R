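#' Run configuration for the segmentation pipeline
#'
#' Bundles and validates every tunable of the four-step procedure (cost,
#' deformation, graph, solve). Defaults follow the OCT layer-segmentation
#' settings: smoothness one voxel per column step, separation 3 to 8 voxels,
#' Gaussian scale 0.3 voxel for both the cost kernel and the deformation
#' regularization, dark-to-bright transitions.
#'
#' @param mode `"non_euclidean"`, `"conventional"` or
#'   `"smoothed_conventional"`.
#' @param lambda number of coupled surfaces.
#' @param dx,dy smoothness bounds (voxels per column step).
#' @param sep separation bounds for adjacent surface pairs (see
#'   [surface_constraints()]).
#' @param sigma_cost Gaussian scale of the cost kernel, voxels.
#' @param sigma_reg Gaussian scale regularizing the deformation field.
#' @param method deformation method, `"neg_gradient"` or `"gvf"`.
#' @param gvf_mu,gvf_iter,gvf_tol GVF energy weight, iteration cap and
#'   convergence tolerance (used when `method = "gvf"`).
#' @param transitions transition polarity per surface, recycled to `lambda`.
#' @param smooth_fwhm lateral FWHM (columns) of the smoothed-conventional
#'   baseline.
#' @param mask_rects list of exclusion rectangles `c(x0, x1, y0, y1)`.
#' @param seed integer seed recorded in the manifest.
#' @param out_dir optional output directory; when set, pipeline entry points
#'   write their results and a run manifest there.
#' @return A validated `negs_config` list.
#' @export
run_config <- function(mode = c("non_euclidean", "conventional", "smoothed_conventional"),
                       lambda = 1L, dx = 1, dy = 1, sep = c(3, 8),
                       sigma_cost = 0.3, sigma_reg = 0.3,
                       method = c("neg_gradient", "gvf"),
                       gvf_mu = 0.1, gvf_iter = 200L, gvf_tol = 1e-4,
                       transitions = "dark_to_bright", smooth_fwhm = 2.355,
                       mask_rects = list(), seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  lambda <- as.integer(lambda)
  cons <- surface_constraints(lambda, dx, dy, if (lambda > 1L) sep else NULL)
  transitions <- rep_len(match.arg(transitions,
                                   c("dark_to_bright", "bright_to_dark"),
                                   several.ok = TRUE), lambda)
  stopifnot(sigma_cost > 0, sigma_reg >= 0, gvf_mu > 0, gvf_iter >= 1,
            smooth_fwhm > 0)
  structure(list(mode = mode, lambda = lambda, cons = cons,
                 sigma_cost = sigma_cost, sigma_reg = sigma_reg,
                 method = method, gvf_mu = gvf_mu, gvf_iter = as.integer(gvf_iter),
                 gvf_tol = gvf_tol, transitions = transitions,
                 smooth_fwhm = smooth_fwhm, mask_rects = mask_rects,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "negs_config")
}

config_echo <- function(cfg) {
  e <- unclass(cfg)
  e$cons <- list(lambda = cfg$cons$lambda, dx = cfg$cons$dx, dy = cfg$cons$dy,
                 sep = cfg$cons$sep)
  e
}

#' Segment terrain-like surfaces in a volume
#'
#' Executes the full pipeline on an input volume: on-surface costs from the
#' Gaussian derivative kernel; for the non-Euclidean mode a deformation
#' field from the (combined) cost, normalized to half-voxel maximum
#' displacement, with costs warped to the deformed node positions; graph
#' construction; minimum closed set by maximum flow; surface extraction, and
#' a thickness map per adjacent surface pair. `"conventional"` skips the
#' deformation (integer-accurate output) and `"smoothed_conventional"`
#' additionally smooths the conventional heights laterally. With
#' `cfg$out_dir` set, surfaces, thickness maps and a JSON run manifest
#' (configuration echo, package version, graph statistics, normalization
#' factor, timings) are written there.
#'
#' @param vol a [new_volume()] (or a path readable by [read_volume()]).
#' @param cfg a [run_config()].
#' @return list with `surfaces` ([surface_set()]), `thickness` (list of
#'   [thickness_map()]s, one per adjacent pair, or empty), `closed_set`,
#'   `graph_stats` and `manifest`.
#' @export
segment_volume <- function(vol, cfg = run_config()) {
  if (is.character(vol)) vol <- read_volume(vol)
  stopifnot_volume(vol)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))
  }
  costs <- stage("cost", lapply(seq_len(cfg$lambda), function(s)
    gaussian_derivative_cost(vol, cfg$sigma_cost, cfg$transitions[s])))
  t_cost <- proc.time()[["elapsed"]]

  D <- NULL; eta <- NA_real_; max_disp <- 0
  if (cfg$mode == "non_euclidean") {
    combined <- costs[[1]]
    if (cfg$lambda > 1L)
      for (s in 2:cfg$lambda) combined$data <- pmin(combined$data, costs[[s]]$data)
    D <- stage("deformation", {
      Draw <- if (cfg$method == "gvf")
        gvf_deformation(combined, cfg$gvf_mu, cfg$gvf_iter, cfg$gvf_tol, cfg$sigma_reg)
      else compute_deformation(combined, cfg$sigma_reg)
      normalize_deformation(Draw)
    })
    eta <- D$eta
    max_disp <- max(abs(D$dx) / D$spacing[1], abs(D$dy) / D$spacing[2],
                    abs(D$dz) / D$spacing[3])
    costs <- stage("warp", lapply(costs, warp_costs, D = D))
  }
  t_def <- proc.time()[["elapsed"]]

  g <- stage("graph", build_graph(costs, D = D, cons = cfg$cons))
  t_graph <- proc.time()[["elapsed"]]
  cs <- stage("solve", min_closed_set(g))
  t_solve <- proc.time()[["elapsed"]]
  surf <- stage("extract", extract_surfaces(cs, g))
  if (cfg$mode == "smoothed_conventional")
    surf <- smooth_surface(surf, cfg$smooth_fwhm)
  thick <- list()
  if (cfg$lambda > 1L)
    thick <- lapply(seq_len(cfg$lambda - 1L), function(s)
      thickness_map(surf, c(s, s + 1L)))

  manifest <- list(
    package = "negseg",
    version = as.character(utils::packageVersion("negseg")),
    config = config_echo(cfg),
    input_dims = dim(vol$data), input_spacing = vol$spacing,
    graph = graph_stats(g), eta = eta, max_relative_displacement = max_disp,
    solver = list(flow_value = cs$flow_value, total_cost = cs$total_cost,
                  cut_size = cs$cut_size),
    timing_s = list(cost = t_cost - t0, deformation = t_def - t_cost,
                    graph = t_graph - t_def, solve = t_solve - t_graph))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_surfaces(surf, file.path(cfg$out_dir, "surfaces.tsv"))
    if (length(thick))
      for (s in seq_along(thick))
        write_surfaces(thick[[s]], file.path(cfg$out_dir, sprintf("thickness_%d.tsv", s)))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(surfaces = surf, thickness = thick, closed_set = cs,
       graph_stats = graph_stats(g), manifest = manifest)
}

# ---- simulation bundles -----------------------------------------------------

preset_spec <- function(preset, seed) {
  ph <- with_seed(seed, stats::runif(6, 0, 2 * pi))
  u <- with_seed(seed + 1L, stats::runif(2))
  switch(preset,
    flat = phantom_spec(24, 12, 200,
      surfaces = list(list(z0 = 90 + 10 * u[1])),
      layer_intensities = c(0.05, 0.85), noise_sd = 0, seed = seed),
    sinusoid = phantom_spec(24, 12, 200,
      surfaces = list(list(z0 = 95 + 10 * u[1], amp = 12, period_x = 24,
                           phase = ph[1])),
      layer_intensities = c(0.05, 0.85), noise_sd = 0.02, seed = seed),
    two_layer_oct = phantom_spec(24, 12, 200,
      surfaces = list(
        list(z0 = 65 + 10 * u[1], amp = 12, period_x = 24, phase = ph[1]),
        list(z0 = 117 + 10 * u[1] + 8 * u[2], amp = 12, period_x = 24,
             phase = ph[1])),
      layer_intensities = c(0.02, 0.45, 0.9), noise_sd = 0.02, seed = seed),
    stop("unknown preset: ", preset))
}

#' Generate a simulation bundle: phantom, downsampled input, mapped reference
#'
#' Builds the full evaluation experiment for one preset: a high-resolution
#' phantom is rendered (continuous boundaries, partial-volume voxels), the
#' volume is downsampled along z by a factor of 10 through the
#' reconstruct/anti-alias/resample chain to produce the "input volume data",
#' and the continuous reference surfaces are mapped onto the downsampled
#' grid. Everything is deterministic under `seed`.
#'
#' @param preset `"flat"`, `"sinusoid"` or `"two_layer_oct"`.
#' @param seed integer seed (drives the random boundary phases and noise).
#' @param out_dir optional directory; input volume (NRRD), reference TSV and
#'   manifest are written there.
#' @return list with `spec`, `input` (downsampled [new_volume()]),
#'   `reference` (mapped [surface_set()]), `truth_hi`, `factors`, `lambda`.
#' @export
simulate_bundle <- function(preset = c("two_layer_oct", "flat", "sinusoid"),
                            seed = 1L, out_dir = NULL) {
  preset <- match.arg(preset)
  spec <- preset_spec(preset, as.integer(seed))
  r <- render_phantom(spec)
  factors <- c(1L, 1L, 10L)
  input <- downsample_volume(r$volume, factors, antialias = TRUE)
  reference <- map_surface_to_grid(r$ground_truth, factors)
  out <- list(preset = preset, seed = as.integer(seed), spec = spec,
              input = input, reference = reference,
              truth_hi = r$ground_truth, factors = factors,
              lambda = length(spec$surfaces))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(input, file.path(out_dir, "input.nrrd"))
    write_surfaces(reference, file.path(out_dir, "reference.tsv"))
    jsonlite::write_json(list(preset = preset, seed = seed, factors = factors,
                              lambda = out$lambda,
                              layer_intensities = spec$layer_intensities,
                              noise_sd = spec$noise_sd),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Evaluate all three modes on a simulation bundle
#'
#' Segments the bundle's input volume with the conventional, smoothed
#' conventional and non-Euclidean pipelines, compares each result to the
#' mapped reference, and assembles the three-row comparison table of mean
#' signed/unsigned surface and thickness errors plus the 0.5-voxel
#' exceedance fractions.
#'
#' @param bundle a [simulate_bundle()] result.
#' @param cfg optional [run_config()] template (mode is overridden per row;
#'   lambda is taken from the bundle).
#' @return list with `table` (data.frame, one row per mode), `reports`
#'   (named list of [surface_errors()] objects) and `results` (named list of
#'   [segment_volume()] outputs).
#' @export
evaluate_bundle <- function(bundle, cfg = NULL) {
  if (is.null(cfg))
    cfg <- run_config(lambda = bundle$lambda, seed = bundle$seed)
  mask <- if (length(cfg$mask_rects))
    rect_mask(dim(bundle$input$data)[1:2], cfg$mask_rects) else NULL
  modes <- c("conventional", "smoothed_conventional", "non_euclidean")
  results <- reports <- list()
  rows <- list()
  for (m in modes) {
    cm <- cfg; cm$mode <- m; cm$out_dir <- NULL
    res <- segment_volume(bundle$input, cm)
    rep <- surface_errors(res$surfaces, bundle$reference, mask = mask)
    results[[m]] <- res
    reports[[m]] <- rep
    su <- rep$summary
    row <- data.frame(mode = m,
                      mean_unsigned_surface = mean(su$mean_unsigned[su$component == "surface"]),
                      mean_signed_surface = mean(su$mean_signed[su$component == "surface"]))
    if (bundle$lambda > 1L) {
      row$mean_unsigned_thickness <- mean(su$mean_unsigned[su$component == "thickness"])
      row$exceedance_0.5 <- exceedance_fraction(rep, 0.5)$fraction
    }
    rows[[m]] <- row
  }
  list(table = do.call(rbind, rows), reports = reports, results = results)
}

# ---- quantization benchmark -------------------------------------------------

#' Two-layer benchmark phantom with random subvoxel boundary phases
#'
#' The standing study conditions of the quantization benchmark: a
#' 24 x 12 x 20 voxel volume with two sinusoidal dark-to-bright boundaries
#' whose base height, thickness and phases are drawn uniformly under `seed`,
#' layer intensities (0, 0.45, 0.9) and additive noise sd 0.02. Boundary
#' heights sweep subvoxel phases quasi-uniformly across columns, so an
#' integer-accurate segmentation incurs the analytic quantization error of
#' 0.25 voxel on average.
#'
#' @param seed integer seed.
#' @return A [phantom_spec()].
#' @export
benchmark_phantom <- function(seed) {
  u <- with_seed(seed * 7L + 3L, stats::runif(5))
  phantom_spec(24, 12, 20,
    surfaces = list(
      list(z0 = 6.5 + u[1], amp = 1.2, period_x = 24, phase = 2 * pi * u[3]),
      list(z0 = 6.5 + u[1] + 4.5 + u[2], amp = 1.2 + 0.4 * sin(2 * pi * u[4]),
           period_x = 24, phase = 2 * pi * u[3] + 0.3)),
    layer_intensities = c(0, 0.45, 0.9), noise_sd = 0.02, seed = seed)
}

#' Run the quantization benchmark suite
#'
#' Renders `n` seeded [benchmark_phantom()]s, segments each with the
#' conventional and non-Euclidean pipelines (the smoothed baseline is
#' derived from the conventional result), and scores every run against the
#' continuous ground truth. Per phantom it records the mean unsigned and
#' signed surface error of each mode, the fraction of columns whose
#' thickness error exceeds 0.5 voxel, and the thickness range of the
#' two-surface solver output.
#'
#' @param n number of phantoms.
#' @param seed base seed; phantom `i` uses `seed + i - 1`.
#' @param progress print one line per phantom.
#' @return A data.frame with one row per phantom and an attribute
#'   `"paired_t"` holding the paired t-test of non-Euclidean vs conventional
#'   mean unsigned surface error.
#' @export
benchmark_suite <- function(n = 50L, seed = 1L, progress = FALSE) {
  cfg <- run_config(lambda = 2L, sep = c(3, 8))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- benchmark_phantom(seed + i - 1L)
    r <- render_phantom(sp)
    res_c <- segment_volume(r$volume, modifyList(cfg, list(mode = "conventional")))
    res_n <- segment_volume(r$volume, modifyList(cfg, list(mode = "non_euclidean")))
    surf_s <- smooth_surface(res_c$surfaces, cfg$smooth_fwhm)
    rep_c <- surface_errors(res_c$surfaces, r$ground_truth)
    rep_n <- surface_errors(res_n$surfaces, r$ground_truth)
    rep_s <- surface_errors(surf_s, r$ground_truth)
    msu <- function(rep) mean(rep$summary$mean_unsigned[rep$summary$component == "surface"])
    mss <- function(rep) mean(rep$summary$mean_signed[rep$summary$component == "surface"])
    th_n <- res_n$thickness[[1]]$values
    th_c <- res_c$thickness[[1]]$values
    rows[[i]] <- data.frame(
      seed = seed + i - 1L,
      unsigned_conventional = msu(rep_c),
      unsigned_smoothed = msu(rep_s),
      unsigned_non_euclidean = msu(rep_n),
      signed_conventional = mss(rep_c),
      signed_non_euclidean = mss(rep_n),
      exceed_conventional = exceedance_fraction(rep_c, 0.5)$fraction,
      exceed_non_euclidean = exceedance_fraction(rep_n, 0.5)$fraction,
      thickness_min = min(th_n, th_c),
      thickness_max = max(th_n, th_c),
      eta = res_n$manifest$eta,
      max_disp = res_n$manifest$max_relative_displacement)
    if (progress)
      message(sprintf("phantom %2d/%d: conv %.3f smooth %.3f ne %.3f", i, n,
                      rows[[i]]$unsigned_conventional,
                      rows[[i]]$unsigned_smoothed,
                      rows[[i]]$unsigned_non_euclidean))
  }
  df <- do.call(rbind, rows)
  attr(df, "paired_t") <- paired_t_test(df$unsigned_non_euclidean,
                                        df$unsigned_conventional)
  df
}
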