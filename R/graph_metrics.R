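#' Threshold a connectivity matrix into a binary graph at a given sparsity
#'
#' Keeps the `K = round-half-up(s * n_pairs)` strongest edges of the
#' correlation matrix (`n_pairs = n(n-1)/2`, so 4005 for 90 regions) and
#' sets all others to zero, producing an undirected, unweighted binary
#' graph. Edges are ranked by signed correlation by default (positive
#' coupling networks, the convention for metabolic covariance); ties are
#' broken lexicographically by `(i, j)` for cross-platform determinism.
#'
#' @param C A [correlation_matrix()] result or bare symmetric matrix.
#' @param s Sparsity, the fraction of possible edges retained, in `(0, 1)`.
#' @param rank_by `"signed"` (default) or `"absolute"` edge ranking.
#' @return Object of class `binary_graph`: list with `adjacency` (0/1
#'   symmetric matrix, zero diagonal), `sparsity`, `n_edges`.
#' @export
threshold_by_sparsity <- function(C, s, rank_by = c("signed", "absolute")) {
  rank_by <- match.arg(rank_by)
  r <- conn_r(C)
  n <- nrow(r)
  if (!(s > 0 && s < 1)) stop("sparsity must lie in (0, 1)", call. = FALSE)
  n_pairs <- n * (n - 1L) / 2L
  K <- floor(s * n_pairs + 0.5)
  if (K < 1L) stop("degenerate threshold: sparsity retains zero edges", call. = FALSE)
  ut <- upper.tri(r)
  idx <- which(ut, arr.ind = TRUE)
  vals <- r[ut]
  if (rank_by == "absolute") vals <- abs(vals)
  ord <- order(-vals, idx[, 1L], idx[, 2L])
  keep <- ord[seq_len(K)]
  A <- matrix(0L, n, n, dimnames = dimnames(r))
  A[idx[keep, , drop = FALSE]] <- 1L
  A <- A + t(A)
  structure(list(adjacency = A, sparsity = s, n_edges = K),
            class = "binary_graph")
}

# Accept a binary_graph or a bare 0/1 adjacency matrix.
graph_adjacency <- function(G) {
  if (inherits(G, "binary_graph")) G$adjacency else as.matrix(G)
}

as_igraph <- function(G) {
  igraph::graph_from_adjacency_matrix(graph_adjacency(G), mode = "undirected",
                                      diag = FALSE)
}

#' @export
print.binary_graph <- function(x, ...) {
  cat("Binary graph:", nrow(x$adjacency), "nodes,", x$n_edges,
      "edges (sparsity", format(x$sparsity), ")\n")
  invisible(x)
}

# All-pairs shortest-path lengths of a binary adjacency matrix via boolean
# matrix powers (distance = smallest k with a length-k walk). Disconnected
# pairs stay Inf. Dense BLAS products, fast for the <= 90-node graphs here.
bfs_distances <- function(A) {
  n <- nrow(A)
  A <- (A > 0) * 1
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  if (n < 3L) return(D)
  Pk <- A
  for (k in 2:(n - 1L)) {
    todo <- is.infinite(D)
    if (!any(todo)) break
    Pk <- (Pk %*% A > 0) * 1
    D[todo & Pk > 0] <- k
  }
  D
}

# Global efficiency of a bare adjacency matrix.
eglob_adjacency <- function(A) {
  n <- nrow(A)
  if (n < 2L) return(0)
  d <- bfs_distances(A)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

#' Global topological metrics of a binary graph
#'
#' Computes the clustering coefficient `Cp` (mean over nodes of the local
#' clustering coefficient, 0 for nodes of degree < 2), the characteristic
#' path length `Lp` (mean shortest-path length over connected ordered
#' pairs; disconnected pairs are excluded and their fraction is available
#' via `Eglob`), the global efficiency `Eglob` (mean of inverse distance
#' over all ordered pairs, with 1/Inf = 0) and the local efficiency `Eloc`
#' (mean over nodes of the global efficiency of the subgraph induced by
#' each node's neighbours, 0 for degree < 2).
#'
#' @param G A [threshold_by_sparsity()] result or 0/1 adjacency matrix.
#' @return Named list with `Cp`, `Lp`, `Eglob`, `Eloc`.
#' @export
global_graph_metrics <- function(G) {
  A <- graph_adjacency(G)
  n <- nrow(A)
  if (n < 2L) stop("graph must have >= 2 nodes", call. = FALSE)
  if (sum(A) == 0) {
    warning("empty graph: all global metrics are zero", call. = FALSE)
    return(list(Cp = 0, Lp = 0, Eglob = 0, Eloc = 0))
  }
  A <- (A > 0) * 1
  deg <- rowSums(A)
  A2 <- A %*% A
  closed <- rowSums(A * A2)            # 2 x triangle count per node
  cp_local <- ifelse(deg >= 2, closed / (deg * (deg - 1)), 0)
  Cp <- mean(cp_local)
  d <- bfs_distances(A)
  finite <- is.finite(d) & row(d) != col(d)
  Lp <- if (any(finite)) mean(d[finite]) else 0
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  Eglob <- sum(inv) / (n * (n - 1))
  eloc_node <- vapply(seq_len(n), function(i) {
    if (deg[i] < 2) return(0)
    nb <- which(A[i, ] == 1)
    eglob_adjacency(A[nb, nb, drop = FALSE])
  }, numeric(1))
  list(Cp = Cp, Lp = Lp, Eglob = Eglob, Eloc = mean(eloc_node))
}

#' Nodal topological metrics of a binary graph
#'
#' Degree (row sum of the adjacency), betweenness (Brandes convention:
#' undirected, unnormalized, with fractional splitting over equal-length
#' shortest paths), and nodal efficiency (mean inverse distance from the
#' node to every other node, 1/Inf = 0).
#'
#' @inheritParams global_graph_metrics
#' @return Data frame with `region`, `degree`, `betweenness`, `efficiency`.
#' @export
nodal_graph_metrics <- function(G) {
  A <- graph_adjacency(G)
  n <- nrow(A)
  if (n < 2L) stop("graph must have >= 2 nodes", call. = FALSE)
  btw <- igraph::betweenness(as_igraph(A), directed = FALSE,
                             normalized = FALSE)
  d <- bfs_distances(A)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  eff <- rowSums(inv) / (n - 1)
  data.frame(region = if (is.null(rownames(A))) paste0("node_", seq_len(n)) else rownames(A),
             degree = as.vector(rowSums(A)), betweenness = as.vector(btw),
             efficiency = as.vector(eff), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Degree-preserving random rewiring (Maslov-Sneppen)
#'
#' Randomizes a binary graph by repeated double-edge swaps that preserve
#' every node's degree exactly, avoiding self-loops and multi-edges.
#' Deterministic given `rng_seed`. Graphs with no legal swap (e.g. the
#' complete graph) are returned unchanged.
#'
#' @inheritParams global_graph_metrics
#' @param n_swaps Number of attempted swaps; default 10 x edge count.
#' @param rng_seed Integer seed.
#' @return A `binary_graph` with the same degree sequence.
#' @export
rewire_preserving_degree <- function(G, n_swaps = NULL, rng_seed = 1L) {
  A <- graph_adjacency(G)
  g <- as_igraph(A)
  m <- igraph::ecount(g)
  if (is.null(n_swaps)) n_swaps <- 10L * m
  set.seed(rng_seed)
  g2 <- igraph::rewire(g, with = igraph::keeping_degseq(loops = FALSE,
                                                        niter = n_swaps))
  A2 <- as.matrix(igraph::as_adjacency_matrix(g2, sparse = FALSE))
  storage.mode(A2) <- "integer"
  dimnames(A2) <- dimnames(A)
  structure(list(adjacency = A2,
                 sparsity = if (inherits(G, "binary_graph")) G$sparsity else NA_real_,
                 n_edges = m),
            class = "binary_graph")
}

#' Small-world normalization against degree-preserving random nulls
#'
#' Normalizes the clustering coefficient and characteristic path length by
#' their means over an ensemble of degree-preserving rewired null graphs:
#' `gamma = Cp / <Cp_rand>`, `lambda = Lp / <Lp_rand>`, and the
#' small-worldness index `sigma = gamma / lambda` (sigma > 1 indicates
#' small-world organization).
#'
#' @inheritParams global_graph_metrics
#' @param n_null Number of rewired null graphs (default 100).
#' @param rng_seed Integer seed; null seeds are derived from it.
#' @param n_swaps Swaps per null; default 10 x edge count.
#' @return Named list with `gamma`, `lambda`, `sigma`, plus the empirical
#'   and mean-null `Cp`/`Lp`.
#' @export
small_world_metrics <- function(G, n_null = 100L, rng_seed = 1L,
                                n_swaps = NULL) {
  stopifnot(n_null >= 1L)
  emp <- global_graph_metrics(G)
  seeds <- derive_stream_seeds(rng_seed, paste0("null_", seq_len(n_null)))
  nulls <- vapply(seeds, function(s) {
    gm <- global_graph_metrics(rewire_preserving_degree(G, n_swaps, s))
    c(gm$Cp, gm$Lp)
  }, numeric(2))
  cp_rand <- mean(nulls[1L, ])
  lp_rand <- mean(nulls[2L, ])
  if (cp_rand == 0 || lp_rand == 0) {
    stop("degenerate null ensemble: mean null Cp or Lp is zero", call. = FALSE)
  }
  gamma <- emp$Cp / cp_rand
  lambda <- emp$Lp / lp_rand
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       Cp = emp$Cp, Lp = emp$Lp, Cp_rand = cp_rand, Lp_rand = lp_rand)
}

#' Area under a metric curve over the sparsity sweep
#'
#' Trapezoidal integral of per-sparsity metric values over the sparsity
#' grid, the scalar summary used as the test statistic for group
#' comparisons.
#'
#' @param values Metric values, one per grid point.
#' @param sparsities Strictly increasing sparsity grid (>= 2 points).
#' @return The trapezoidal integral (scalar).
#' @export
auc_over_sparsity <- function(values, sparsities) {
  if (length(values) != length(sparsities)) {
    stop("values and sparsities have different lengths", call. = FALSE)
  }
  if (length(sparsities) < 2L || any(diff(sparsities) <= 0)) {
    stop("sparsities must be a strictly increasing grid of >= 2 points",
         call. = FALSE)
  }
  pracma::trapz(sparsities, values)
}

#' Global metric curves across a sparsity sweep
#'
#' @param C A [correlation_matrix()] result or bare correlation matrix.
#' @param sparsities Sparsity grid.
#' @param rank_by Edge ranking passed to [threshold_by_sparsity()].
#' @return Matrix (length(sparsities) x 4) with columns `Cp`, `Lp`,
#'   `Eglob`, `Eloc`; rownames are the sparsities.
#' @export
global_metric_curves <- function(C, sparsities = sparsity_grid(),
                                 rank_by = "signed") {
  out <- t(vapply(sparsities, function(s) {
    unlist(global_graph_metrics(threshold_by_sparsity(C, s, rank_by)))
  }, numeric(4)))
  rownames(out) <- format(sparsities)
  out
}

#' Nodal metric curves across a sparsity sweep
#'
#' @inheritParams global_metric_curves
#' @param metric One of `"degree"`, `"betweenness"`, `"efficiency"`.
#' @return Matrix (regions x length(sparsities)).
#' @export
nodal_metric_curves <- function(C, metric = c("degree", "betweenness", "efficiency"),
                                sparsities = sparsity_grid(), rank_by = "signed") {
  metric <- match.arg(metric)
  one <- function(A) {
    switch(metric,
      degree = as.vector(rowSums(A)),
      betweenness = as.vector(igraph::betweenness(as_igraph(A),
                                                  directed = FALSE,
                                                  normalized = FALSE)),
      efficiency = {
        inv <- 1 / bfs_distances(A)
        diag(inv) <- 0
        as.vector(rowSums(ifelse(is.finite(inv), inv, 0)) / (nrow(A) - 1))
      })
  }
  vapply(sparsities, function(s) {
    one(graph_adjacency(threshold_by_sparsity(C, s, rank_by)))
  }, numeric(nrow(conn_r(C))))
}

#' Default sparsity sweep (0.10 to 0.50 in steps of 0.01)
#'
#' @param min,max,step Grid limits and spacing.
#' @return Numeric vector of sparsities.
#' @export
sparsity_grid <- function(min = 0.10, max = 0.50, step = 0.01) {
  if (!(min > 0 && min < max && max < 1 && step > 0)) {
    stop("sparsity grid requires 0 < min < max < 1 and step > 0", call. = FALSE)
  }
  seq(min, max, by = step)
}
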