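#' Smoothness and separation constraints for surface segmentation
#'
#' @param lambda number of coupled surfaces (>= 1).
#' @param dx,dy nonnegative maximum allowed change of a surface's z
#'   coordinate (in voxels of the deformed continuous coordinate) per unit
#'   step along x and y.
#' @param sep for `lambda > 1`: separation bounds between adjacent surface
#'   pairs, either a length-2 vector `c(delta_low, delta_up)` recycled to all
#'   pairs or a `(lambda - 1) x 2` matrix; surface `s+1` must lie between
#'   `delta_low` and `delta_up` voxels above surface `s`.
#' @return A `negs_constraints` object.
#' @export
surface_constraints <- function(lambda = 1L, dx = 1, dy = 1, sep = NULL) {
  lambda <- as.integer(lambda)
  if (lambda < 1L) stop("`lambda` must be >= 1")
  if (dx < 0 || dy < 0) stop("`dx` and `dy` must be >= 0")
  if (lambda > 1L) {
    if (is.null(sep)) stop("separation bounds `sep` required when lambda > 1")
    sep <- matrix(as.numeric(sep), nrow = lambda - 1L, ncol = 2L,
                  byrow = is.null(dim(sep)))
    if (any(sep[, 1] > sep[, 2])) stop("need delta_low <= delta_up for every pair")
    if (any(sep[, 1] < 0)) stop("separation bounds must be >= 0")
  } else sep <- matrix(numeric(0), 0, 2)
  structure(list(lambda = lambda, dx = dx, dy = dy, sep = sep),
            class = "negs_constraints")
}

#' Node weights from a column of costs
#'
#' The weight of the bottom node is its cost; every other node's weight is
#' its cost minus the cost of the node immediately below, so that the total
#' weight of a closed set whose column prefix ends at depth `k` telescopes
#' back to the on-surface cost at `k`.
#'
#' @param cost_column numeric vector of costs, ordered bottom to top.
#' @return Numeric vector of node weights.
#' @export
node_weights <- function(cost_column) {
  if (length(cost_column) == 0L) stop("empty cost column")
  if (any(!is.finite(cost_column))) stop("cost column must be finite")
  c(cost_column[1], diff(cost_column))
}

#' Bottom-most compatible neighbors between two node columns
#'
#' For every node `i` of column A, finds the lowest node `j` of column B that
#' can lie on the target surface together with it, where compatibility means
#' `z'_B(j) - z'_A(i)` falls inside `window` (`c(-delta, delta)` for a
#' smoothness bound, `c(delta_low, delta_up)` for a separation bound). If no
#' node of B falls inside a node's window, the node whose `z'` is nearest to
#' the window is admitted as its sole neighbor and flagged.
#'
#' @param zA,zB strictly increasing deformed z positions of the two columns.
#' @param delta symmetric smoothness bound; ignored if `window` is given.
#' @param window explicit compatibility window `c(lo, hi)` on
#'   `z'_B(j) - z'_A(i)`.
#' @return A list with `bottom` (0-based bottom-most neighbor index per node
#'   of A), `top` (0-based top-most, by the symmetric rule) and `fallback`
#'   (logical, per node of A).
#' @export
neighbor_ranges <- function(zA, zB, delta = 1, window = c(-delta, delta)) {
  if (is.unsorted(zA, strictly = TRUE) || is.unsorted(zB, strictly = TRUE))
    stop("column z' positions must be strictly increasing")
  if (window[1] > window[2]) stop("invalid window")
  n <- length(zB)
  lo <- zA + window[1]
  hi <- zA + window[2]
  bm <- findInterval(lo, zB, left.open = TRUE) + 1L   # min j: zB[j] >= lo
  tm <- findInterval(hi, zB)                          # max j: zB[j] <= hi
  fallback <- bm > n | tm < 1L | bm > tm
  if (any(fallback)) {
    idx <- which(fallback)
    bmf <- pmin(bm[idx], n)
    below <- pmax(bmf - 1L, 1L)
    d_above <- abs(zB[bmf] - pmin(pmax(zB[bmf], lo[idx]), hi[idx]))
    d_below <- abs(zB[below] - pmin(pmax(zB[below], lo[idx]), hi[idx]))
    near <- ifelse(d_below <= d_above, below, bmf)
    bm[idx] <- near
    tm[idx] <- near
  }
  list(bottom = bm - 1L, top = tm - 1L, fallback = fallback)
}

#' Build the segmentation graph
#'
#' Constructs the node-weighted directed graph whose minimum closed set
#' encodes the optimal set of `lambda` terrain-like surfaces. Without a
#' deformation field this is the conventional Euclidean construction (node
#' z' equal to the integer voxel index); with a normalized field the nodes
#' take their deformed positions `z' = z + D_z / spacing_z` and all
#' inter-column and inter-subgraph neighbor ranges are recomputed on the
#' deformed coordinates, so the non-Euclidean graph has exactly the same
#' node and arc counts as the conventional one. Arcs (held as neighbor-range
#' tables):
#' intra-column `k -> k-1` (surface crosses each column once);
#' inter-column arcs to the bottom-most compatible neighbor under the
#' 4-neighborhood (smoothness `dx`, `dy`);
#' inter-subgraph arcs between corresponding columns of adjacent subgraphs
#' enforcing `z'_(s+1) - z'_s` within the pair's separation bounds;
#' base arcs linking the bottom nodes so the bottom slab is always a closed
#' set.
#'
#' @param costs one cost volume (`lambda = 1`) or a list of `lambda` cost
#'   volumes on one grid (warped costs for the non-Euclidean pipeline, raw
#'   for the conventional one).
#' @param D `NULL` for the conventional graph, or a normalized
#'   [compute_deformation()] field on the same grid.
#' @param cons a [surface_constraints()].
#' @param scale integer scaling applied to costs for the exact max-flow
#'   backend (costs are multiplied by `scale` and rounded).
#' @return A `negs_graph` object.
#' @export
build_graph <- function(costs, D = NULL, cons = surface_constraints(), scale = 1e6) {
  if (inherits(costs, "negs_cost")) costs <- list(costs)
  if (length(costs) != cons$lambda)
    stop(sprintf("need %d cost volume(s) for lambda = %d", cons$lambda, cons$lambda))
  d <- dim(costs[[1]]$data)
  for (cv in costs) {
    if (!inherits(cv, "negs_cost")) stop("costs must be negs_cost objects")
    if (!identical(dim(cv$data), d)) stop("all cost volumes must share one grid")
  }
  X <- d[1]; Y <- d[2]; Z <- d[3]
  if (!is.null(D)) {
    if (!inherits(D, "negs_deformation")) stop("`D` must be a negs_deformation")
    if (!identical(dim(D$dz), d)) stop("`D` grid mismatch")
    if (is.na(D$eta)) stop("`D` must be normalized (see normalize_deformation)")
    zprime <- apply_deformation(D)$z
  } else {
    zprime <- array(rep(0:(Z - 1), each = X * Y), d)
  }

  cost <- array(0, c(X, Y, Z, cons$lambda))
  for (s in seq_len(cons$lambda)) cost[, , , s] <- costs[[s]]$data
  cost_int <- round(cost * scale)
  w_int <- cost_int
  if (Z > 1)
    w_int[, , 2:Z, ] <- cost_int[, , 2:Z, , drop = FALSE] -
      cost_int[, , 1:(Z - 1), , drop = FALSE]

  # neighbor tables: bottom-most neighbor (1-based R index into the target
  # column) for the four lateral directions, NA beyond the grid edge
  dirs <- list(xp = c(1L, 0L), xm = c(-1L, 0L), yp = c(0L, 1L), ym = c(0L, -1L))
  delta_of <- c(xp = cons$dx, xm = cons$dx, yp = cons$dy, ym = cons$dy)
  bm <- lapply(dirs, function(d0) array(NA_integer_, d))
  n_fallback <- 0L
  for (y in seq_len(Y)) for (x in seq_len(X)) {
    zA <- zprime[x, y, ]
    for (nm in names(dirs)) {
      x2 <- x + dirs[[nm]][1]; y2 <- y + dirs[[nm]][2]
      if (x2 < 1L || x2 > X || y2 < 1L || y2 > Y) next
      nr <- neighbor_ranges(zA, zprime[x2, y2, ], delta = delta_of[[nm]])
      bm[[nm]][x, y, ] <- nr$bottom + 1L
      n_fallback <- n_fallback + sum(nr$fallback)
    }
  }

  # separation tables between adjacent subgraphs (columns share zprime)
  sep_up <- sep_down <- vector("list", max(cons$lambda - 1L, 0L))
  if (cons$lambda > 1L) {
    for (s in seq_len(cons$lambda - 1L)) {
      up <- down <- array(NA_integer_, d)
      for (y in seq_len(Y)) for (x in seq_len(X)) {
        zc <- zprime[x, y, ]
        u <- neighbor_ranges(zc, zc, window = cons$sep[s, ])
        v <- neighbor_ranges(zc, zc, window = -rev(cons$sep[s, ]))
        up[x, y, ] <- u$bottom + 1L
        down[x, y, ] <- v$bottom + 1L
        n_fallback <- n_fallback + sum(u$fallback) + sum(v$fallback)
      }
      sep_up[[s]] <- up
      sep_down[[s]] <- down
    }
  }
  if (n_fallback > 0L)
    message(sprintf("build_graph: %d empty neighbor range(s) resolved by nearest-node fallback",
                    n_fallback))

  structure(list(dims = d, lambda = cons$lambda, cons = cons, zprime = zprime,
                 cost = cost, cost_int = cost_int, w_int = w_int, scale = scale,
                 bm = bm, sep_up = sep_up, sep_down = sep_down,
                 deformed = !is.null(D),
                 eta = if (is.null(D)) NA_real_ else D$eta,
                 max_rel_disp = if (is.null(D)) 0 else
                   max(abs(D$dx) / D$spacing[1], abs(D$dy) / D$spacing[2],
                       abs(D$dz) / D$spacing[3]),
                 spacing = costs[[1]]$spacing, n_fallback = n_fallback),
            class = "negs_graph")
}

#' @export
print.negs_graph <- function(x, ...) {
  st <- graph_stats(x)
  cat(sprintf("<negs_graph %s> %d x %d x %d, lambda = %d, %d nodes, %d arcs (%d fallback)\n",
              if (x$deformed) "non-Euclidean" else "Euclidean",
              x$dims[1], x$dims[2], x$dims[3], x$lambda,
              st$n_nodes, st$n_arcs_total, x$n_fallback))
  invisible(x)
}

#' Node and arc counts of a segmentation graph
#'
#' @param g a `negs_graph`.
#' @return A list of counts per arc type, serializable as JSON.
#' @export
graph_stats <- function(g) {
  d <- g$dims
  X <- d[1]; Y <- d[2]; Z <- d[3]; L <- g$lambda
  n_pairs_x <- 2L * (X - 1L) * Y             # ordered adjacent column pairs
  n_pairs_y <- 2L * X * (Y - 1L)
  st <- list(
    n_nodes = L * X * Y * Z,
    n_arcs_intra = L * X * Y * (Z - 1L),
    n_arcs_inter = L * (n_pairs_x + n_pairs_y) * Z,
    n_arcs_sep = 2L * (L - 1L) * X * Y * Z,
    n_arcs_base = n_pairs_x + n_pairs_y + 2L * (L - 1L) * X * Y,
    n_fallback = g$n_fallback,
    deformed = g$deformed)
  st$n_arcs_total <- st$n_arcs_intra + st$n_arcs_inter + st$n_arcs_sep + st$n_arcs_base
  st
}

# Directed constraint arcs of the graph as 1-based node index vectors.
# Node (x, y, k, s) has linear index x + X(y-1) + XY(k-1) + XYZ(s-1).
graph_edges <- function(g) {
  d <- g$dims
  X <- d[1]; Y <- d[2]; Z <- d[3]; L <- g$lambda
  nxyz <- X * Y * Z
  lin <- function(x, y, k, s) x + X * (y - 1L) + X * Y * (k - 1L) + nxyz * (s - 1L)
  from <- list(); to <- list(); e <- 0L
  add <- function(f, t) { e <<- e + 1L; from[[e]] <<- f; to[[e]] <<- t }

  xg <- rep(seq_len(X), times = Y * Z)
  yg <- rep(rep(seq_len(Y), each = X), times = Z)
  kg <- rep(seq_len(Z), each = X * Y)
  for (s in seq_len(L)) {
    base_s <- nxyz * (s - 1L)
    node <- seq_len(nxyz) + base_s
    # intra-column k -> k-1
    sel <- kg > 1L
    add(node[sel], node[sel] - X * Y)
    # inter-column to bottom-most neighbor
    shift <- c(xp = 1L, xm = -1L, yp = X, ym = -X)
    for (nm in names(g$bm)) {
      bmv <- as.vector(g$bm[[nm]])
      ok <- !is.na(bmv)
      tgt_col <- (xg + X * (yg - 1L))[ok] + shift[[nm]]
      add(node[ok], tgt_col + X * Y * (bmv[ok] - 1L) + base_s)
    }
  }
  # inter-subgraph separation arcs
  if (L > 1L) for (s in seq_len(L - 1L)) {
    up <- as.vector(g$sep_up[[s]])
    down <- as.vector(g$sep_down[[s]])
    colv <- xg + X * (yg - 1L)
    add(colv + X * Y * (kg - 1L) + nxyz * (s - 1L),
        colv + X * Y * (up - 1L) + nxyz * s)
    add(colv + X * Y * (kg - 1L) + nxyz * s,
        colv + X * Y * (down - 1L) + nxyz * (s - 1L))
  }
  # base arcs: bottom nodes of adjacent columns (both ways) and across
  # subgraphs, making the bottom slab closed
  bx <- rep(seq_len(X), times = Y)
  by <- rep(seq_len(Y), each = X)
  for (s in seq_len(L)) {
    b <- lin(bx, by, 1L, s)
    selx <- bx < X
    add(b[selx], lin(bx[selx] + 1L, by[selx], 1L, s))
    add(lin(bx[selx] + 1L, by[selx], 1L, s), b[selx])
    sely <- by < Y
    add(b[sely], lin(bx[sely], by[sely] + 1L, 1L, s))
    add(lin(bx[sely], by[sely] + 1L, 1L, s), b[sely])
  }
  if (L > 1L) for (s in seq_len(L - 1L)) {
    b1 <- lin(bx, by, 1L, s); b2 <- lin(bx, by, 1L, s + 1L)
    add(b1, b2); add(b2, b1)
  }
  list(from = unlist(from), to = unlist(to))
}
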