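test_that("node weights telescope back to the costs", {
  expect_equal(node_weights(c(5, 3, 2)), c(5, -2, -1))
  set.seed(31)
  for (i in 1:20) {
    cc <- runif(64, -5, 5)
    w <- node_weights(cc)
    expect_equal(cumsum(w), cc, tolerance = 1e-12)
    # closed set of depth k has total weight c(k): explicit summation oracle
    k <- sample(64, 1)
    expect_equal(sum(w[1:k]), cc[k], tolerance = 1e-12)
  }
})

test_that("neighbor ranges reproduce the conventional case and the worked window", {
  z <- as.numeric(0:9)
  nr <- neighbor_ranges(z, z, delta = 1)
  expect_identical(nr$bottom, pmax(0:9 - 1L, 0L))
  expect_identical(nr$top, pmin(0:9 + 1L, 9L))
  expect_false(any(nr$fallback))

  nr2 <- neighbor_ranges(2.4, c(0.6, 1.6, 2.6, 3.4), delta = 1)
  expect_identical(nr2$bottom, 1L)   # window [1.4, 3.4] -> z' = 1.6
  expect_identical(nr2$top, 3L)

  expect_error(neighbor_ranges(c(1, 1), z), "strictly increasing")
})

test_that("neighbor ranges match a brute-force scan and stay properly ordered", {
  for (seed in 1:200) {
    DA <- random_deformation(c(1, 1, 8), seed)
    DB <- random_deformation(c(1, 1, 8), seed + 5000L)
    zA <- apply_deformation(DA)$z[1, 1, ]
    zB <- apply_deformation(DB)$z[1, 1, ]
    nr <- neighbor_ranges(zA, zB, delta = 1)
    brute <- vapply(zA, function(z) {
      ok <- which(abs(zB - z) <= 1)
      if (length(ok)) ok[1] - 1L else NA_integer_
    }, 0L)
    expect_identical(nr$bottom[!is.na(brute)], brute[!is.na(brute)])
    expect_true(all(diff(nr$bottom) >= 0L))   # proper ordering
    expect_true(all(diff(nr$top) >= 0L))
  }
})

test_that("an undeformed graph reproduces the conventional construction", {
  set.seed(32)
  d <- c(3, 3, 4)
  cost <- as_cost_volume(array(runif(prod(d)), d))
  g <- build_graph(cost)
  expect_identical(g$zprime, array(rep(0:3, each = 9), d))
  for (nm in c("xp", "xm", "yp", "ym")) {
    tab <- g$bm[[nm]]
    inside <- !is.na(tab)
    k <- array(rep(1:4, each = 9), d)
    expect_identical(tab[inside], pmax(k[inside] - 1L, 1L))
  }
  st <- graph_stats(g)
  expect_identical(st$n_nodes, 36L)
  expect_identical(st$n_arcs_intra, 27L)
})

test_that("separation windows clip to the column and flag fallbacks at the top", {
  d <- c(1, 1, 12)
  costs <- list(as_cost_volume(array(0, d)), as_cost_volume(array(0, d)))
  g <- suppressMessages(
    build_graph(costs, cons = surface_constraints(2, sep = c(3, 8))))
  up <- g$sep_up[[1]][1, 1, ]
  # node k (1-based) of subgraph 1 is compatible with k+3 .. k+8 of subgraph 2
  expect_identical(up[1:9], 1:9 + 3L)
  expect_identical(up[10:12], rep(12L, 3))   # empty window -> nearest (top)
  down <- g$sep_down[[1]][1, 1, ]
  expect_identical(down[4:12], pmax(4:12 - 8L, 1L))
  expect_identical(down[1:3], rep(1L, 3))    # below-bottom window -> node 0
})

test_that("deformation leaves node and arc counts unchanged", {
  set.seed(33)
  d <- c(4, 3, 6)
  for (i in 1:10) {
    cost <- as_cost_volume(array(runif(prod(d)), d))
    g0 <- build_graph(cost)
    D <- random_deformation(d, 600L + i)
    g1 <- suppressMessages(build_graph(warp_costs(cost, D), D = D))
    s0 <- graph_stats(g0); s1 <- graph_stats(g1)
    expect_identical(s0[c("n_nodes", "n_arcs_intra", "n_arcs_inter",
                          "n_arcs_sep", "n_arcs_base", "n_arcs_total")],
                     s1[c("n_nodes", "n_arcs_intra", "n_arcs_inter",
                          "n_arcs_sep", "n_arcs_base", "n_arcs_total")])
    e0 <- negseg:::graph_edges(g0); e1 <- negseg:::graph_edges(g1)
    expect_identical(length(e0$from), length(e1$from))
  }
})

test_that("every feasible surface's lower set is closed under the graph arcs", {
  # self-closure, checked exhaustively on a tiny deformed single-surface graph
  g <- random_small_graph(77L, lambda = 1L, dims = c(2L, 2L, 4L), deformed = TRUE)
  expect_identical(g$n_fallback, 0L)
  en <- enumerate_closed_sets(g, feasible = "ideal")
  ed <- negseg:::graph_edges(g)
  d <- g$dims
  for (r in seq_len(min(nrow(en$table), 200L))) {
    tops <- en$table$tops[r, ]
    memb <- logical(prod(d))
    for (ci in seq_len(4)) {
      x <- (ci - 1L) %% 2L + 1L; y <- (ci - 1L) %/% 2L + 1L
      ks <- seq_len(tops[ci])
      memb[x + d[1] * (y - 1L) + d[1] * d[2] * (ks - 1L)] <- TRUE
    }
    expect_true(all(memb[ed$to[memb[ed$from]]]))  # no arc leaves the set
  }
  # and with no fallback the graph arcs encode exactly the ideal windows
  en_g <- enumerate_closed_sets(g, feasible = "graph")
  expect_identical(en$n_feasible, en_g$n_feasible)
  expect_identical(en$table$cost_int, en_g$table$cost_int)
})
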