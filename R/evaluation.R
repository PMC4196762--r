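#' Surface-position and thickness errors against a reference
#'
#' Per-column signed errors `e(x, y) = z_pred - z_ref - bias` for every
#' surface and, when two or more surfaces are present, for the thickness of
#' each adjacent pair; aggregated into mean signed and unsigned errors with
#' their standard deviations over the unmasked columns. `bias` subtracts a
#' fixed, known offset between the two grids (with the package's own
#' voxel-center mapping convention the downsampling boundary shift is
#' already absorbed by [map_surface_to_grid()], so the default is 0; pass a
#' value when comparing against surfaces mapped under another convention).
#'
#' @param pred a [surface_set()] of predictions.
#' @param ref the reference [surface_set()] on the same lateral grid.
#' @param bias fixed offset subtracted from all signed surface errors.
#' @param mask optional logical matrix, `TRUE` = exclude the column
#'   (rectangular exclusion regions such as an optic-nerve-head box; see
#'   [rect_mask()]).
#' @return A `negs_errors` object: `surface` (per-column signed error array
#'   `nx x ny x lambda`), `thickness` (array for adjacent pairs, or `NULL`),
#'   and a `summary` data.frame with one row per surface/pair holding
#'   mean_signed, sd_signed, mean_unsigned, sd_unsigned and n.
#' @export
surface_errors <- function(pred, ref, bias = 0, mask = NULL) {
  dp <- dim(pred$heights); dr <- dim(ref$heights)
  if (!identical(dp, dr))
    stop(sprintf("grid mismatch: prediction %s vs reference %s",
                 paste(dp, collapse = "x"), paste(dr, collapse = "x")))
  if (is.null(mask)) mask <- matrix(FALSE, dp[1], dp[2])
  e <- pred$heights - ref$heights - bias
  for (s in seq_len(dp[3])) e[, , s][mask] <- NA_real_
  et <- NULL
  if (dp[3] >= 2L) {
    et <- array(0, c(dp[1], dp[2], dp[3] - 1L))
    for (s in seq_len(dp[3] - 1L)) {
      # thickness is a difference of surfaces: the fixed bias cancels
      et[, , s] <- (pred$heights[, , s + 1] - pred$heights[, , s]) -
                   (ref$heights[, , s + 1] - ref$heights[, , s])
      et[, , s][mask] <- NA_real_
    }
  }
  agg <- function(a, label, id) {
    v <- as.vector(a); v <- v[!is.na(v)]
    data.frame(component = label, id = id,
               mean_signed = mean(v), sd_signed = stats::sd(v),
               mean_unsigned = mean(abs(v)), sd_unsigned = stats::sd(abs(v)),
               n = length(v))
  }
  rows <- lapply(seq_len(dp[3]), function(s) agg(e[, , s], "surface", s))
  if (!is.null(et))
    rows <- c(rows, lapply(seq_len(dp[3] - 1L),
                           function(s) agg(et[, , s], "thickness", s)))
  structure(list(surface = e, thickness = et, bias = bias, mask = mask,
                 mode = pred$mode, summary = do.call(rbind, rows)),
            class = "negs_errors")
}

#' @export
print.negs_errors <- function(x, ...) {
  cat(sprintf("<negs_errors %s> bias %.4g, %d masked columns\n",
              x$mode, x$bias, sum(x$mask)))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Rectangular exclusion mask
#'
#' @param dims lateral grid size `c(nx, ny)`.
#' @param rects list of rectangles `c(x0, x1, y0, y1)` (0-based, inclusive).
#' @return Logical matrix, `TRUE` inside any rectangle.
#' @export
rect_mask <- function(dims, rects) {
  m <- matrix(FALSE, dims[1], dims[2])
  for (r in rects) {
    xs <- max(r[1], 0):min(r[2], dims[1] - 1)
    ys <- max(r[3], 0):min(r[4], dims[2] - 1)
    m[xs + 1L, ys + 1L] <- TRUE
  }
  m
}

#' Paired two-sided t-test on per-dataset means
#'
#' Thin wrapper around [stats::t.test()] on the differences `a - b` with the
#' degenerate cases pinned down: identically zero differences give
#' `t = 0, p = 1`; zero variance with nonzero mean gives `p` at the machine
#' floor with `degenerate = TRUE`.
#'
#' @param a,b numeric vectors of equal length (>= 2), one value per dataset.
#' @return list with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("`a` and `b` must have equal length >= 2")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, p = 1, df = length(d) - 1L, mean_diff = 0,
                  degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p = .Machine$double.xmin,
                df = length(d) - 1L, mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_diff = unname(tt$estimate), degenerate = FALSE)
}

#' Fraction of columns whose unsigned error exceeds a threshold
#'
#' Also returns the ascending sorted unsigned-error curve (the per-A-scan
#' error profile used to compare methods over a whole cohort).
#'
#' @param report a [surface_errors()] result.
#' @param threshold error threshold in voxels.
#' @param component `"surface"` or `"thickness"`.
#' @param id surface or pair index within the component.
#' @return list with `fraction`, `n`, and `sorted_errors`.
#' @export
exceedance_fraction <- function(report, threshold = 0.5,
                                component = c("thickness", "surface"), id = 1L) {
  component <- match.arg(component)
  a <- if (component == "surface") report$surface else report$thickness
  if (is.null(a)) stop("report has no thickness component")
  v <- abs(as.vector(a[, , id]))
  v <- v[!is.na(v)]
  list(fraction = mean(v > threshold), n = length(v), sorted_errors = sort(v))
}

#' Write an error report as JSON (aggregates) and TSV (per-column errors)
#'
#' @param report a [surface_errors()] result.
#' @param prefix output path prefix (`<prefix>.json`, `<prefix>_surface.tsv`,
#'   `<prefix>_thickness.tsv`, `<prefix>_sorted.tsv`).
#' @return The written paths, invisibly.
#' @export
write_error_report <- function(report, prefix) {
  jp <- paste0(prefix, ".json")
  jsonlite::write_json(list(mode = report$mode, bias = report$bias,
                            summary = report$summary),
                       jp, auto_unbox = TRUE, digits = NA)
  sp <- paste0(prefix, "_surface.tsv")
  write_surfaces(surface_set(report$surface), sp)
  paths <- c(jp, sp)
  if (!is.null(report$thickness)) {
    tp <- paste0(prefix, "_thickness.tsv")
    write_surfaces(surface_set(report$thickness), tp)
    cp <- paste0(prefix, "_sorted.tsv")
    ex <- exceedance_fraction(report)
    utils::write.table(data.frame(rank = seq_along(ex$sorted_errors),
                                  unsigned_error = ex$sorted_errors),
                       cp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, tp, cp)
  }
  invisible(paths)
}
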