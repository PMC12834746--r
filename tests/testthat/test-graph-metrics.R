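ring_lattice <- function(n, k) {
  # each node connected to its k nearest neighbours on each side
  A <- matrix(0L, n, n)
  for (d in 1:k) {
    for (i in 1:n) {
      j <- ((i - 1 + d) %% n) + 1
      A[i, j] <- A[j, i] <- 1L
    }
  }
  A
}

test_that("sparsity thresholding keeps exactly the strongest K edges", {
  set.seed(1)
  r <- matrix(runif(16, -1, 1), 4); r <- (r + t(r)) / 2; diag(r) <- 1
  G <- threshold_by_sparsity(r, 0.5)
  expect_equal(G$n_edges, 3L)   # round-half-up(0.5 * 6)
  expect_equal(sum(G$adjacency) / 2, 3)
  expect_equal(G$adjacency, t(G$adjacency))
  expect_equal(diag(G$adjacency), rep(0L, 4))
  kept <- r[upper.tri(r)][G$adjacency[upper.tri(r)] == 1]
  dropped <- r[upper.tri(r)][G$adjacency[upper.tri(r)] == 0]
  expect_gte(min(kept), max(dropped))

  # 90 nodes at s = 0.10: round-half-up(400.5) = 401 edges
  C90 <- default_base_correlation(90)
  expect_equal(threshold_by_sparsity(C90, 0.10)$n_edges, 401)

  # all off-diagonal equal: ties resolved to lexicographically first (i, j)
  # pairs, i.e. (1,2), (1,3), (1,4)
  tie <- matrix(0.5, 4, 4); diag(tie) <- 1
  Gt <- threshold_by_sparsity(tie, 0.5)
  kept <- which(Gt$adjacency == 1 & upper.tri(tie), arr.ind = TRUE)
  kept <- kept[order(kept[, 1], kept[, 2]), ]
  expect_equal(unname(kept), cbind(c(1L, 1L, 1L), c(2L, 3L, 4L)))

  expect_error(threshold_by_sparsity(r, 0), "\\(0, 1\\)")
  expect_error(threshold_by_sparsity(diag(30), 0.001), "degenerate")
})

test_that("signed versus absolute edge ranking differ as designed", {
  r <- matrix(0, 3, 3); diag(r) <- 1
  r[1, 2] <- r[2, 1] <- -0.9
  r[1, 3] <- r[3, 1] <- 0.3
  r[2, 3] <- r[3, 2] <- 0.1
  expect_equal(threshold_by_sparsity(r, 1 / 3, "signed")$adjacency[1, 3], 1L)
  expect_equal(threshold_by_sparsity(r, 1 / 3, "absolute")$adjacency[1, 2], 1L)
})

test_that("global metrics reproduce hand-computed closed forms", {
  K4 <- matrix(1L, 4, 4); diag(K4) <- 0L
  m <- global_graph_metrics(K4)
  expect_equal(m, list(Cp = 1, Lp = 1, Eglob = 1, Eloc = 1))

  P4 <- matrix(0L, 4, 4)
  P4[cbind(1:3, 2:4)] <- 1L; P4 <- P4 + t(P4)
  m <- global_graph_metrics(P4)
  expect_equal(m$Cp, 0)
  expect_equal(m$Lp, 10 / 6)
  expect_equal(m$Eglob, 13 / 18)

  expect_warning(m0 <- global_graph_metrics(matrix(0L, 3, 3)), "empty")
  expect_equal(m0, list(Cp = 0, Lp = 0, Eglob = 0, Eloc = 0))
})

test_that("nodal metrics reproduce hand-computed closed forms", {
  star <- matrix(0L, 5, 5)
  star[1, 2:5] <- 1L; star <- star + t(star)
  nm <- nodal_graph_metrics(star)
  expect_equal(nm$degree, c(4, 1, 1, 1, 1))
  expect_equal(nm$betweenness, c(6, 0, 0, 0, 0))
  expect_equal(nm$efficiency, c(1, 0.625, 0.625, 0.625, 0.625))

  P3 <- matrix(0L, 3, 3)
  P3[cbind(1:2, 2:3)] <- 1L; P3 <- P3 + t(P3)
  expect_equal(nodal_graph_metrics(P3)$betweenness[2], 1)
})

test_that("all graph metrics match brute-force oracles on random graphs", {
  for (s in 1:100) {
    n <- sample(4:12, 1)
    A <- random_adjacency(n, runif(1, 0.15, 0.8), seed = s)
    if (sum(A) == 0) next
    m <- global_graph_metrics(A)
    o <- oracle_global_metrics(A)
    expect_equal(m$Cp, o$Cp, tolerance = 1e-12)
    expect_equal(m$Lp, o$Lp, tolerance = 1e-12)
    expect_equal(m$Eglob, o$Eglob, tolerance = 1e-12)
    expect_equal(m$Eloc, o$Eloc, tolerance = 1e-12)
    nm <- nodal_graph_metrics(A)
    expect_equal(nm$degree, unname(rowSums(A)), tolerance = 1e-12)
    expect_equal(nm$betweenness, oracle_betweenness(A), tolerance = 1e-9)
    expect_equal(nm$efficiency, oracle_nodal_efficiency(A), tolerance = 1e-12)
    expect_equal(sum(nm$degree), sum(A))
    expect_true(all(nm$betweenness >= 0))
  }
})

test_that("global efficiency dominates 1/Lp on connected graphs (Jensen)", {
  checked <- 0
  for (s in 1:50) {
    A <- random_adjacency(10, 0.4, seed = 500 + s)
    d <- suppressWarnings(global_graph_metrics(A))
    if (d$Eglob == 0) next
    D <- oracle_dist_matrix(A)
    if (any(is.infinite(D))) next   # only connected graphs
    expect_gte(d$Eglob, 1 / d$Lp - 1e-12)
    checked <- checked + 1
  }
  expect_gt(checked, 10)
})

test_that("global efficiency is monotone over nested sparsity thresholds", {
  C <- correlation_matrix(matrix(rnorm(30 * 15), 30, 15))
  grid <- seq(0.10, 0.50, by = 0.05)
  curves <- global_metric_curves(C, grid)
  expect_true(all(diff(curves[, "Eglob"]) >= -1e-12))
  # structural invariants across the sweep
  for (s in grid) {
    G <- threshold_by_sparsity(C, s)
    expect_equal(G$n_edges, floor(s * 15 * 14 / 2 + 0.5))
    expect_equal(G$adjacency, t(G$adjacency))
    expect_equal(diag(G$adjacency), rep(0L, 15))
  }
})

test_that("degree-preserving rewiring keeps degrees and randomizes structure", {
  A <- ring_lattice(24, 2)
  for (s in 1:10) {
    G2 <- rewire_preserving_degree(A, rng_seed = s)
    expect_equal(rowSums(G2$adjacency), rowSums(A))
    expect_equal(diag(G2$adjacency), rep(0L, 24))
    expect_true(all(G2$adjacency %in% c(0L, 1L)))
  }
  # complete graph has no legal swap
  K5 <- matrix(1L, 5, 5); diag(K5) <- 0L
  expect_equal(rewire_preserving_degree(K5, rng_seed = 1)$adjacency, K5)
  # rewiring destroys lattice clustering in nearly every run
  cp0 <- global_graph_metrics(A)$Cp
  drops <- vapply(1:100, function(s) {
    global_graph_metrics(rewire_preserving_degree(A, rng_seed = s))$Cp < cp0
  }, logical(1))
  expect_gte(mean(drops), 0.95)
})

test_that("small-world normalization behaves at its fixed points", {
  K6 <- matrix(1L, 6, 6); diag(K6) <- 0L
  sw <- small_world_metrics(K6, n_null = 5, rng_seed = 1)
  expect_identical(sw$gamma, 1)
  expect_identical(sw$lambda, 1)
  expect_identical(sw$sigma, 1)

  lat <- ring_lattice(40, 4)
  sw_lat <- small_world_metrics(lat, n_null = 20, rng_seed = 2)
  expect_gt(sw_lat$gamma, 2)
  expect_equal(sw_lat$sigma, sw_lat$gamma / sw_lat$lambda, tolerance = 1e-12)
})

test_that("AUC over sparsity matches trapezoid geometry and a Riemann oracle", {
  grid <- seq(0.10, 0.50, by = 0.01)
  expect_equal(auc_over_sparsity(rep(1, length(grid)), grid), 0.40)
  ramp <- (grid - 0.10) / 0.40
  expect_equal(auc_over_sparsity(ramp, grid), 0.20)
  set.seed(6)
  vals <- runif(length(grid))
  # midpoint Riemann sums on each segment are exact for the piecewise-linear
  # interpolant, giving an independent route to the same integral
  oracle <- sum(vapply(seq_len(length(grid) - 1), function(k) {
    xs <- seq(grid[k], grid[k + 1], length.out = 201)
    mid <- (xs[-1] + xs[-201]) / 2
    ys <- approx(grid, vals, xout = mid)$y
    sum(ys * diff(xs))
  }, numeric(1)))
  expect_equal(auc_over_sparsity(vals, grid), oracle, tolerance = 1e-9)
  expect_error(auc_over_sparsity(1:3, c(0.1, 0.2)), "length")
  expect_error(auc_over_sparsity(1:2, c(0.2, 0.1)), "increasing")
})
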