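# CSR-style BFS over a directed edge list; returns logical reachability from src.
bfs_reachable <- function(nv, ef, et, src) {
  ord <- order(ef)
  ef_s <- ef[ord]; et_s <- et[ord]
  ptr <- c(0L, cumsum(tabulate(ef_s, nv)))
  visited <- logical(nv)
  visited[src] <- TRUE
  frontier <- src
  while (length(frontier)) {
    cnt <- ptr[frontier + 1L] - ptr[frontier]
    has <- cnt > 0L
    if (!any(has)) break
    idx <- sequence(cnt[has], from = ptr[frontier[has]] + 1L)
    nbr <- unique(et_s[idx])
    frontier <- nbr[!visited[nbr]]
    visited[frontier] <- TRUE
  }
  visited
}

#' Minimum-cost closed set of a segmentation graph
#'
#' Solves the minimum closed set problem by the standard s-t maximum-flow
#' reduction: every negative-weight node gets a source arc of capacity
#' `-w`, every positive-weight node a sink arc of capacity `w`, and all
#' constraint arcs get a capacity exceeding the total absolute weight
#' (a safe finite stand-in for infinity). The bottom node of every column
#' additionally has a large constant subtracted from its weight, which makes
#' the base slab mandatory, so the minimum closed set is never empty and
#' always defines `lambda` surfaces. The source side of a minimum cut is
#' canonicalized by breadth-first reachability in the residual graph, giving
#' the inclusion-minimal minimum closed set (the lowest optimal upper
#' envelope) independently of the max-flow backend. Capacities are the
#' graph's integer-scaled weights, on which the push-relabel backend
#' (igraph) is exact.
#'
#' @param g a [build_graph()] result.
#' @return A `negs_closed_set`: logical `membership [X, Y, Z, lambda]`,
#'   1-based per-column top indices `tops [X, Y, lambda]`, the surface cost
#'   `total_cost` (sum of on-surface costs of all chosen nodes, in original
#'   cost units), and solver statistics (`flow_value`, arc and cut counts).
#' @export
min_closed_set <- function(g) {
  if (!inherits(g, "negs_graph")) stop("`g` must be a negs_graph")
  d <- g$dims
  X <- d[1]; Y <- d[2]; Z <- d[3]; L <- g$lambda
  ntot <- X * Y * Z * L
  w <- as.vector(g$w_int)
  kg <- rep(rep(seq_len(Z), each = X * Y), times = L)
  M <- 1 + sum(abs(w))
  w[kg == 1L] <- w[kg == 1L] - M           # mandatory base slab
  big <- 1 + sum(abs(w))

  ed <- graph_edges(g)
  src <- ntot + 1L; snk <- ntot + 2L
  neg <- which(w < 0); pos <- which(w > 0)
  ef <- c(ed$from, rep(src, length(neg)), pos)
  et <- c(ed$to, neg, rep(snk, length(pos)))
  cap <- c(rep(big, length(ed$from)), -w[neg], w[pos])

  gr <- igraph::make_graph(rbind(ef, et), n = ntot + 2L, directed = TRUE)
  mf <- igraph::max_flow(gr, source = src, target = snk, capacity = cap)
  flow <- mf$flow

  rf <- c(ef[flow < cap - 0.5], et[flow > 0.5])
  rt <- c(et[flow < cap - 0.5], ef[flow > 0.5])
  reach <- bfs_reachable(ntot + 2L, rf, rt, src)
  if (reach[snk]) stop("internal error: sink reachable after max flow")
  members <- reach[seq_len(ntot)]

  weight_int <- sum(w[members])
  # duality: min cut value + sum of negative weights = closed set weight
  dual <- sum(w[w < 0]) + mf$value
  if (abs(dual - weight_int) > 0.5)
    stop("max-flow duality violated: flow does not certify the closed set")

  memb <- array(members, c(X, Y, Z, L))
  tops <- apply(memb, c(1, 2, 4), function(col) {
    if (!col[1]) stop("closed set misses a base node")
    m <- which(col)
    if (any(diff(m) != 1L)) stop("column membership is not a downward-closed prefix")
    max(m)
  })
  cost_int <- weight_int + L * X * Y * M
  structure(list(membership = memb, tops = tops,
                 total_cost = cost_int / g$scale, cost_int = cost_int,
                 flow_value = mf$value,
                 n_arcs = length(ef), cut_size = length(mf$cut)),
            class = "negs_closed_set")
}

#' @export
print.negs_closed_set <- function(x, ...) {
  d <- dim(x$membership)
  cat(sprintf("<negs_closed_set> %d x %d columns, lambda = %d, total cost %.6g\n",
              d[1], d[2], d[4], x$total_cost))
  invisible(x)
}

# Feasibility of a full surface configuration `tops` [X, Y, L] (1-based)
# against the graph: "ideal" checks the continuous windows; "graph" checks
# closure under the graph's neighbor tables (identical except where the
# nearest-node fallback fired).
config_feasible <- function(g, tops, feasible = c("graph", "ideal")) {
  feasible <- match.arg(feasible)
  d <- g$dims; X <- d[1]; Y <- d[2]; L <- g$lambda
  zp <- g$zprime
  zat <- function(x, y, k) zp[cbind(x, y, k)]
  for (s in seq_len(L)) {
    t_s <- tops[, , s, drop = FALSE]; dim(t_s) <- c(X, Y)
    for (dir in list(c(1L, 0L, 1L), c(0L, 1L, 2L))) {
      dxs <- dir[1]; dys <- dir[2]
      delta <- if (dir[3] == 1L) g$cons$dx else g$cons$dy
      xa <- rep(seq_len(X - dxs), times = Y - dys)
      ya <- rep(seq_len(Y - dys), each = X - dxs)
      ta <- t_s[cbind(xa, ya)]; tb <- t_s[cbind(xa + dxs, ya + dys)]
      if (feasible == "ideal") {
        dz <- zat(xa + dxs, ya + dys, tb) - zat(xa, ya, ta)
        if (any(abs(dz) > delta + 1e-12)) return(FALSE)
      } else {
        nm_f <- if (dir[3] == 1L) "xp" else "yp"
        nm_b <- if (dir[3] == 1L) "xm" else "ym"
        if (any(tb < g$bm[[nm_f]][cbind(xa, ya, ta)])) return(FALSE)
        if (any(ta < g$bm[[nm_b]][cbind(xa + dxs, ya + dys, tb)])) return(FALSE)
      }
    }
  }
  if (L > 1L) for (s in seq_len(L - 1L)) {
    xa <- rep(seq_len(X), times = Y); ya <- rep(seq_len(Y), each = X)
    t1 <- tops[, , s, drop = FALSE]; dim(t1) <- c(X, Y)
    t2 <- tops[, , s + 1L, drop = FALSE]; dim(t2) <- c(X, Y)
    ta <- t1[cbind(xa, ya)]; tb <- t2[cbind(xa, ya)]
    if (feasible == "ideal") {
      dz <- zat(xa, ya, tb) - zat(xa, ya, ta)
      if (any(dz < g$cons$sep[s, 1] - 1e-12 | dz > g$cons$sep[s, 2] + 1e-12))
        return(FALSE)
    } else {
      if (any(tb < g$sep_up[[s]][cbind(xa, ya, ta)])) return(FALSE)
      if (any(ta < g$sep_down[[s]][cbind(xa, ya, tb)])) return(FALSE)
    }
  }
  TRUE
}

#' Exhaustively enumerate feasible surfaces of a small graph
#'
#' Verification oracle: enumerates every per-column top-index configuration,
#' filters by the pairwise constraints, and sums the on-surface costs.
#' `feasible = "graph"` keeps exactly the configurations whose down-sets are
#' closed sets of the built graph (including nearest-node fallback arcs);
#' `"ideal"` filters by the continuous smoothness/separation windows
#' instead. The two coincide whenever no fallback fired.
#'
#' @param g a small `negs_graph` (`lambda` <= 2).
#' @param feasible `"graph"` or `"ideal"` (see above).
#' @param max_combos guard on the number of enumerated configurations.
#' @return A list: `table` (data.frame of configurations sorted by cost, with
#'   a `tops` matrix column of 1-based per-column-and-subgraph indices and
#'   `cost` in original units), `min_cost`, `min_cost_int` and `argmin` (the
#'   cheapest configuration, ties broken toward the pointwise-lowest one).
#' @export
enumerate_closed_sets <- function(g, feasible = c("graph", "ideal"),
                                  max_combos = 1e6) {
  feasible <- match.arg(feasible)
  d <- g$dims; X <- d[1]; Y <- d[2]; Z <- d[3]; L <- g$lambda
  if (L > 2L) stop("enumeration oracle supports lambda <= 2")
  ncol_ <- X * Y
  if (Z^(ncol_ * L) > max_combos)
    stop(sprintf("combination count %.3g exceeds guard %.3g", Z^(ncol_ * L), max_combos))

  combos <- as.matrix(expand.grid(rep(list(seq_len(Z)), ncol_)))  # n x (X*Y)
  # smoothness filter for one subgraph, vectorized over configurations
  smooth_ok <- function(cmb) {
    ok <- rep(TRUE, nrow(cmb))
    colxy <- cbind(rep(seq_len(X), times = Y), rep(seq_len(Y), each = X))
    for (ci in seq_len(ncol_)) {
      x <- colxy[ci, 1]; y <- colxy[ci, 2]
      for (dir in list(c(1L, 0L), c(0L, 1L))) {
        x2 <- x + dir[1]; y2 <- y + dir[2]
        if (x2 > X || y2 > Y) next
        cj <- x2 + X * (y2 - 1L)
        delta <- if (dir[1] == 1L) g$cons$dx else g$cons$dy
        za <- g$zprime[x, y, cmb[, ci]]
        zb <- g$zprime[x2, y2, cmb[, cj]]
        if (feasible == "ideal") {
          ok <- ok & abs(zb - za) <= delta + 1e-12
        } else {
          nmf <- if (dir[1] == 1L) "xp" else "yp"
          nmb <- if (dir[1] == 1L) "xm" else "ym"
          ok <- ok & cmb[, cj] >= g$bm[[nmf]][cbind(x, y, cmb[, ci])] &
                     cmb[, ci] >= g$bm[[nmb]][cbind(x2, y2, cmb[, cj])]
        }
      }
    }
    ok
  }
  feas1 <- combos[smooth_ok(combos), , drop = FALSE]

  cost_of <- function(cmb, s) {
    tot <- numeric(nrow(cmb))
    for (ci in seq_len(ncol_)) {
      x <- (ci - 1L) %% X + 1L; y <- (ci - 1L) %/% X + 1L
      tot <- tot + g$cost_int[cbind(x, y, cmb[, ci], s)]
    }
    tot
  }

  if (L == 1L) {
    cost_int <- cost_of(feas1, 1L)
    tops <- feas1
  } else {
    n1 <- nrow(feas1)
    if (as.double(n1)^2 > max_combos)
      stop("feasible single-surface count too large for pairing")
    i1 <- rep(seq_len(n1), times = n1)
    i2 <- rep(seq_len(n1), each = n1)
    ok <- rep(TRUE, length(i1))
    for (ci in seq_len(ncol_)) {
      x <- (ci - 1L) %% X + 1L; y <- (ci - 1L) %/% X + 1L
      k1 <- feas1[i1, ci]; k2 <- feas1[i2, ci]
      if (feasible == "ideal") {
        dz <- g$zprime[cbind(x, y, k2)] - g$zprime[cbind(x, y, k1)]
        ok <- ok & dz >= g$cons$sep[1, 1] - 1e-12 & dz <= g$cons$sep[1, 2] + 1e-12
      } else {
        ok <- ok & k2 >= g$sep_up[[1]][cbind(x, y, k1)] &
                   k1 >= g$sep_down[[1]][cbind(x, y, k2)]
      }
    }
    i1 <- i1[ok]; i2 <- i2[ok]
    cost_int <- cost_of(feas1[i1, , drop = FALSE], 1L) +
                cost_of(feas1[i2, , drop = FALSE], 2L)
    tops <- cbind(feas1[i1, , drop = FALSE], feas1[i2, , drop = FALSE])
  }
  if (length(cost_int) == 0L) stop("no feasible surface configuration")
  # sort by cost, then lexicographically by tops so the argmin tie-break is
  # the pointwise-lowest optimal configuration
  ord <- do.call(order, c(list(cost_int), lapply(seq_len(ncol(tops)), function(j) tops[, j])))
  tops <- tops[ord, , drop = FALSE]
  cost_int <- cost_int[ord]
  argmin <- array(tops[1, ], c(X, Y, L))
  list(table = data.frame(cost = cost_int / g$scale, cost_int = cost_int,
                          tops = I(tops)),
       min_cost = cost_int[1] / g$scale, min_cost_int = cost_int[1],
       argmin = argmin, n_feasible = length(cost_int))
}

#' Single-surface dynamic program on one B-scan
#'
#' Independent 2D oracle: minimizes the total cost of one surface across the
#' columns of a single B-scan under `|z'(i) - z'(i+1)| <= delta`, by dynamic
#' programming; this equals the max-flow solution restricted to 2D. Among
#' cost-optimal surfaces the pointwise-lowest one is returned (the same
#' canonical tie-break as the inclusion-minimal minimum closed set).
#'
#' @param cost2d numeric matrix `X x Z` of on-surface costs (columns of the
#'   B-scan along rows).
#' @param delta smoothness bound per column step.
#' @param zprime optional `X x Z` matrix of deformed z positions (defaults
#'   to integer positions `0..Z-1`).
#' @param scale integer cost scaling, matching [build_graph()].
#' @return list with `tops` (1-based indices per column), `heights`
#'   (deformed z of the chosen nodes), `cost` and `cost_int`.
#' @export
dp_single_surface_2d <- function(cost2d, delta = 1, zprime = NULL, scale = 1e6) {
  X <- nrow(cost2d); Z <- ncol(cost2d)
  if (is.null(zprime))
    zprime <- matrix(0:(Z - 1), X, Z, byrow = TRUE)
  ci <- round(cost2d * scale)
  f <- matrix(Inf, X, Z); b <- matrix(Inf, X, Z)
  f[1, ] <- ci[1, ]
  if (X > 1) for (x in 2:X) {
    nr <- neighbor_ranges(zprime[x, ], zprime[x - 1, ], delta = delta)
    for (j in seq_len(Z)) {
      if (nr$fallback[j]) next
      rng <- (nr$bottom[j] + 1L):(nr$top[j] + 1L)
      f[x, j] <- ci[x, j] + min(f[x - 1, rng])
    }
  }
  b[X, ] <- ci[X, ]
  if (X > 1) for (x in (X - 1):1) {
    nr <- neighbor_ranges(zprime[x, ], zprime[x + 1, ], delta = delta)
    for (j in seq_len(Z)) {
      if (nr$fallback[j]) next
      rng <- (nr$bottom[j] + 1L):(nr$top[j] + 1L)
      b[x, j] <- ci[x, j] + min(b[x + 1, rng])
    }
  }
  opt <- min(f[X, ])
  if (!is.finite(opt)) stop("no feasible 2D surface under the given delta")
  tops <- integer(X)
  for (x in seq_len(X))
    tops[x] <- which(f[x, ] + b[x, ] - ci[x, ] <= opt + 0.5)[1]
  list(tops = tops, heights = zprime[cbind(seq_len(X), tops)],
       cost = opt / scale, cost_int = opt)
}
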