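# Independent brute-force oracles. These deliberately share no code with the
# package: per-node queue-based BFS, explicit triangle enumeration, shortest
# path counting for betweenness, and literal step-up FDR.

oracle_bfs_dist <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n)
  d[s] <- 0
  queue <- s
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (w in which(A[v, ] > 0)) {
      if (is.infinite(d[w])) {
        d[w] <- d[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  d
}

oracle_dist_matrix <- function(A) {
  t(vapply(seq_len(nrow(A)), function(s) oracle_bfs_dist(A, s),
           numeric(nrow(A))))
}

oracle_global_metrics <- function(A) {
  n <- nrow(A)
  cp <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      links <- links + A[nb[a], nb[b]]
    }
    links / (k * (k - 1) / 2)
  }, numeric(1))
  D <- oracle_dist_matrix(A)
  off <- row(D) != col(D)
  fin <- off & is.finite(D)
  Lp <- if (any(fin)) mean(D[fin]) else 0
  Eglob <- sum(1 / D[fin]) / (n * (n - 1))
  eloc <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- A[nb, nb, drop = FALSE]
    Ds <- oracle_dist_matrix(sub)
    offs <- row(Ds) != col(Ds) & is.finite(Ds)
    m <- length(nb)
    sum(1 / Ds[offs]) / (m * (m - 1))
  }, numeric(1))
  list(Cp = mean(cp), Lp = Lp, Eglob = Eglob, Eloc = mean(eloc))
}

# Betweenness by explicit shortest-path counting: sigma[s,t] = number of
# shortest s-t paths; dependency of pair (s,t) on v is sigma_sv*sigma_vt if
# v lies on a shortest path. Unordered pairs, so sum over s < t.
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_dist_matrix(A)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    ord <- order(D[s, ])
    sigma[s, s] <- 1
    for (v in ord) {
      if (v == s || is.infinite(D[s, v])) next
      preds <- which(A[v, ] > 0 & D[s, ] == D[s, v] - 1)
      sigma[s, v] <- sum(sigma[s, preds])
    }
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (is.infinite(D[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  btw
}

oracle_nodal_efficiency <- function(A) {
  D <- oracle_dist_matrix(A)
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    sum(1 / d[is.finite(d)]) / (n - 1)
  }, numeric(1))
}

# Literal Benjamini-Hochberg step-up: q_i = min_{j >= rank(i)} p_(j)*m/j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(p[ord][i:m] * m / (i:m))
  }
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Alternating-projection nearest-PSD correlation repair (independent of the
# package's clip-and-rescale): project onto PSD cone, then onto unit
# diagonal, until convergence.
oracle_nearest_psd_corr <- function(R, iters = 500) {
  X <- R
  for (i in seq_len(iters)) {
    e <- eigen((X + t(X)) / 2, symmetric = TRUE)
    X <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    diag(X) <- 1
  }
  X
}

random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(runif(n * (n - 1) / 2) < p)
  A + t(A)
}

# Small helper cohort: two groups from one multivariate normal (null case).
null_suv_pair <- function(n_per_group, n_rois, seed, rho = 0.3) {
  set.seed(seed)
  R <- matrix(rho, n_rois, n_rois)
  diag(R) <- 1
  suv <- MASS::mvrnorm(2 * n_per_group, rep(1, n_rois), R * 0.01)
  colnames(suv) <- paste0("ROI_", seq_len(n_rois))
  list(suv = suv,
       group = factor(rep(c("A", "B"), each = n_per_group)))
}
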