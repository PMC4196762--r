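#' Set of terrain-like surfaces over a lateral grid
#'
#' Container for `lambda` real-valued height fields `z_s(x, y)` in
#' voxel-center z coordinates of the analysis grid (one height per surface
#' per column). Ground-truth reference surfaces use `mode = "reference"`;
#' segmentation results carry the mode of the pipeline that produced them.
#'
#' @param heights numeric array `nx x ny x lambda` (a matrix is taken as one
#'   surface).
#' @param mode one of `"reference"`, `"conventional"`, `"non_euclidean"`,
#'   `"smoothed_conventional"`.
#' @param spacing per-axis voxel size of the grid the heights refer to.
#' @return A `negs_surfaces` object.
#' @export
surface_set <- function(heights, mode = "reference", spacing = c(1, 1, 1)) {
  if (is.matrix(heights)) heights <- array(heights, c(dim(heights), 1L))
  if (!is.array(heights) || length(dim(heights)) != 3L)
    stop("`heights` must be an nx x ny x lambda array")
  mode <- match.arg(mode, c("reference", "conventional", "non_euclidean",
                            "smoothed_conventional"))
  structure(list(heights = heights, mode = mode, spacing = as.numeric(spacing)),
            class = "negs_surfaces")
}

#' @export
print.negs_surfaces <- function(x, ...) {
  d <- dim(x$heights)
  cat(sprintf("<negs_surfaces %s> %d x %d columns, %d surface(s), z range [%.3f, %.3f]\n",
              x$mode, d[1], d[2], d[3], min(x$heights), max(x$heights)))
  invisible(x)
}

#' Extract surfaces from a minimum closed set
#'
#' The upper envelope of the closed set — per column and subgraph, the
#' top-most member node — is the optimal surface. Each height is the
#' deformed position `z'` of that node, which is where subvoxel accuracy
#' enters; on an undeformed graph the heights are the integer node indices
#' (conventional mode).
#'
#' @param cs a [min_closed_set()] result.
#' @param g the `negs_graph` it was computed on.
#' @return A [surface_set()] of mode `"non_euclidean"` or `"conventional"`.
#' @export
extract_surfaces <- function(cs, g) {
  if (!inherits(cs, "negs_closed_set")) stop("`cs` must be a negs_closed_set")
  d <- g$dims; L <- g$lambda
  h <- array(0, c(d[1], d[2], L))
  for (s in seq_len(L)) {
    t_s <- cs$tops[, , s]
    h[, , s] <- g$zprime[cbind(rep(seq_len(d[1]), d[2]),
                               rep(seq_len(d[2]), each = d[1]),
                               as.vector(t_s))]
  }
  surface_set(h, mode = if (g$deformed) "non_euclidean" else "conventional",
              spacing = g$spacing)
}

#' Resample surfaces to another lateral grid
#'
#' Bilinear interpolation of each height field at the target column centers,
#' using the package-wide voxel-center phase convention: target column
#' `(i, j)` (0-based, spacing ratio `r`) sits at source lateral coordinate
#' `i * r_x + (r_x - 1) / 2` (and likewise in y). Requests outside the
#' source extent are clamped with a warning.
#'
#' @param s a [surface_set()].
#' @param target_dims integer length-2 target lateral grid size.
#' @param ratio lateral sampling ratio source/target per axis (default
#'   derived as `dim/target_dims`).
#' @return A [surface_set()] on the target grid.
#' @export
resample_surface <- function(s, target_dims, ratio = NULL) {
  d <- dim(s$heights)
  target_dims <- as.integer(target_dims)
  if (is.null(ratio)) ratio <- d[1:2] / target_dims
  cx <- (0:(target_dims[1] - 1)) * ratio[1] + (ratio[1] - 1) / 2
  cy <- (0:(target_dims[2] - 1)) * ratio[2] + (ratio[2] - 1) / 2
  if (min(cx, cy) < -1e-9 || max(cx) > d[1] - 1 + 1e-9 || max(cy) > d[2] - 1 + 1e-9)
    warning("target grid extends beyond the source extent; clamping")
  xi <- matrix(cx, target_dims[1], target_dims[2])
  yi <- matrix(cy, target_dims[1], target_dims[2], byrow = TRUE)
  out <- array(0, c(target_dims, d[3]))
  for (k in seq_len(d[3]))
    out[, , k] <- interp2(s$heights[, , k], as.vector(xi), as.vector(yi))
  surface_set(out, mode = s$mode, spacing = c(s$spacing[1:2] * ratio, s$spacing[3]))
}

#' Thickness map of the layer bounded by two surfaces
#'
#' `S(x, y) = z_upper(x, y) - z_lower(x, y)` per column, in voxels of the
#' analysis grid; masked columns are set to `NA`.
#'
#' @param s a [surface_set()] with at least two surfaces.
#' @param pair `c(lower_id, upper_id)` surface indices.
#' @param mask optional logical matrix, `TRUE` = exclude the column.
#' @return A `negs_thickness` object with matrix `values` and the `mask`.
#' @export
thickness_map <- function(s, pair = c(1L, 2L), mask = NULL) {
  d <- dim(s$heights)
  if (max(pair) > d[3]) stop("surface index out of range")
  v <- s$heights[, , pair[2]] - s$heights[, , pair[1]]
  if (any(v < 0)) stop("negative thickness: surface ordering violated upstream")
  if (!is.null(mask)) v[mask] <- NA_real_
  structure(list(values = v, pair = pair,
                 mask = if (is.null(mask)) matrix(FALSE, d[1], d[2]) else mask),
            class = "negs_thickness")
}

#' Laterally smooth surface heights
#'
#' Gaussian smoothing of each height field in x and y (reflect boundary),
#' the post-processing baseline against which subvoxel graph search is
#' compared: it can only average the integer staircase of a conventional
#' result, not recover the partial-volume information.
#'
#' @param s a [surface_set()].
#' @param fwhm full width at half maximum of the lateral kernel, in columns
#'   (sd = fwhm / 2.355; the default gives sd = 1 column).
#' @return The smoothed [surface_set()], mode `"smoothed_conventional"`.
#' @export
smooth_surface <- function(s, fwhm = 2.355) {
  if (fwhm <= 0) stop("`fwhm` must be > 0")
  sd <- fwhm / (2 * sqrt(2 * log(2)))
  d <- dim(s$heights)
  a <- s$heights
  k <- gaussian_kernel(sd)
  for (ax in 1:2) if (d[ax] > 1) a <- conv_axis(a, k, ax)
  surface_set(a, mode = "smoothed_conventional", spacing = s$spacing)
}

# ---- TSV and PNG output -----------------------------------------------------

#' Write surfaces as TSV
#'
#' Format: comment header lines `#surface_id<TAB><id>` (one per surface),
#' then rows `x<TAB>y<TAB>surface_id<TAB>z` with 0-based integer column
#' coordinates and real-valued z; missing heights are written as `NA`.
#'
#' @param s a [surface_set()] (or a `negs_thickness`, written as surface 1).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_surfaces <- function(s, path) {
  if (inherits(s, "negs_thickness"))
    s <- surface_set(array(s$values, c(dim(s$values), 1L)))
  d <- dim(s$heights)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("#surface_id\t%d", seq_len(d[3])), con)
  writeLines(sprintf("#mode\t%s", s$mode), con)
  df <- data.frame(x = rep(rep(0:(d[1] - 1), d[2]), d[3]),
                   y = rep(rep(0:(d[2] - 1), each = d[1]), d[3]),
                   surface_id = rep(seq_len(d[3]), each = d[1] * d[2]),
                   z = as.vector(s$heights))
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read surfaces from TSV written by [write_surfaces()]
#'
#' @param path input file.
#' @return A [surface_set()].
#' @export
read_surfaces <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  mode_line <- hdr[startsWith(hdr, "#mode")]
  mode <- if (length(mode_line)) sub("#mode\t", "", mode_line[1]) else "reference"
  df <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                          col.names = c("x", "y", "surface_id", "z"),
                          na.strings = "NA")
  nx <- max(df$x) + 1L; ny <- max(df$y) + 1L; ns <- max(df$surface_id)
  h <- array(NA_real_, c(nx, ny, ns))
  h[cbind(df$x + 1L, df$y + 1L, df$surface_id)] <- df$z
  surface_set(h, mode = mode)
}

#' Render a thickness map (or any scalar field) as a grayscale PNG heat map
#'
#' @param values numeric matrix; `NA` rendered black.
#' @param path output PNG path.
#' @param range optional `c(lo, hi)` display range (defaults to data range).
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(values, path, range = NULL) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("PNG rendering needs the png package")
  if (inherits(values, "negs_thickness")) values <- values$values
  if (is.null(range)) range <- range(values, na.rm = TRUE)
  v <- (values - range[1]) / max(range[2] - range[1], .Machine$double.eps)
  v[is.na(v)] <- 0
  png::writePNG(t(pmin(pmax(v, 0), 1)), path)
  invisible(path)
}
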