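#' Group-level metabolic connectivity matrix
#'
#' Pearson correlation, across subjects of one group, between the normalized
#' SUV values of every pair of regions. This is a group-level construct: one
#' matrix per group, with regions as rows/columns. Zero-variance regions
#' yield r = 0 on their rows/columns (with a warning) rather than NaN, so
#' downstream thresholding stays total.
#'
#' @param suv Subjects x regions matrix for a single group (>= 3 subjects,
#'   no missing values).
#' @param group Optional group label stored on the result.
#' @return Object of class `connectivity_matrix`: list with `r` (regions x
#'   regions, unit diagonal), `n_subjects`, `group`.
#' @export
correlation_matrix <- function(suv, group = NA_character_) {
  suv <- as.matrix(suv)
  if (nrow(suv) < 3L) stop("need >= 3 subjects to correlate", call. = FALSE)
  if (anyNA(suv)) stop("SUV matrix contains missing values", call. = FALSE)
  sds <- apply(suv, 2, sd)
  r <- suppressWarnings(cor(suv))
  if (any(sds == 0)) {
    warning("zero-variance region(s): ",
            paste(colnames(suv)[sds == 0], collapse = ", "),
            "; their correlations are set to 0", call. = FALSE)
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 1
  structure(list(r = r, n_subjects = nrow(suv), group = group),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("Metabolic connectivity matrix:", nrow(x$r), "regions,",
      x$n_subjects, "subjects",
      if (!is.na(x$group)) paste0("(group ", x$group, ")"), "\n")
  invisible(x)
}

# Accept either a connectivity_matrix or a bare correlation matrix.
conn_r <- function(C) {
  if (inherits(C, "connectivity_matrix")) C$r else as.matrix(C)
}

#' Seed-based connectivity profile
#'
#' Extracts the connectivity of one seed region to every other region.
#'
#' @param C A [correlation_matrix()] result (or bare correlation matrix
#'   with region dimnames).
#' @param seed Seed region name.
#' @return Named numeric vector of length `n_regions - 1`.
#' @export
seed_connectivity <- function(C, seed) {
  r <- conn_r(C)
  idx <- match_region(seed, rownames(r))
  r[idx, -idx]
}

#' Compare two independent-group correlations (Fisher r-to-z)
#'
#' Two-sample test of equality of correlation coefficients estimated in two
#' independent groups: `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) +
#' 1/(n2-3))` with a two-sided normal p-value. Vectorized over edges.
#'
#' @param r1,r2 Correlation coefficients (`|r| < 1`).
#' @param n1,n2 Group sizes (`>= 4`).
#' @return List with `z` and `p`.
#' @export
compare_edge_correlations <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1)) {
    stop("|r| = 1 gives an infinite z transform; correlations must satisfy |r| < 1",
         call. = FALSE)
  }
  if (any(c(n1, n2) < 4L)) stop("group sizes must be >= 4", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Subject-level permutation test for an edge correlation difference
#'
#' Permutation alternative to [compare_edge_correlations()]: group labels
#' are randomly reassigned to subjects (group sizes preserved) and the
#' difference of Fisher-transformed correlations recomputed; the two-tailed
#' empirical p uses the add-one convention.
#'
#' @param x1,y1 Seed and target SUV values for group 1 subjects.
#' @param x2,y2 Seed and target SUV values for group 2 subjects.
#' @param n_perm Number of relabellings (default 10000).
#' @param rng_seed Seed for the relabelling stream.
#' @return List with `observed` (atanh difference), `p`, `n_perm`.
#' @export
edge_permutation_test <- function(x1, y1, x2, y2, n_perm = 10000L,
                                  rng_seed = 1L) {
  n1 <- length(x1); n2 <- length(x2)
  stopifnot(length(y1) == n1, length(y2) == n2, n1 >= 4L, n2 >= 4L)
  xs <- c(x1, x2); ys <- c(y1, y2)
  stat <- function(idx1) {
    atanh(cor(xs[idx1], ys[idx1])) - atanh(cor(xs[-idx1], ys[-idx1]))
  }
  obs <- stat(seq_len(n1))
  set.seed(rng_seed)
  null <- vapply(seq_len(n_perm), function(b) {
    stat(sample.int(n1 + n2, n1))
  }, numeric(1))
  list(observed = obs,
       p = (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm),
       n_perm = n_perm)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q-values with enforced monotonicity, order preserved
#' relative to the input.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as input.
#' @export
fdr_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Seed-edge between-group tests with FDR control
#'
#' Tests, for every edge from the seed region, whether the group-level
#' metabolic connectivity differs between two groups. The FDR family is the
#' `n_regions - 1` seed edges (Fisher r-to-z test per edge,
#' Benjamini-Hochberg across edges).
#'
#' @param C1,C2 [correlation_matrix()] results for the two groups.
#' @param seed Seed region name.
#' @return Data frame with `region`, `r_group1`, `r_group2`, `z`, `p`, `q`,
#'   ordered as in the connectivity matrix.
#' @export
seed_edge_tests <- function(C1, C2, seed) {
  r1 <- seed_connectivity(C1, seed)
  r2 <- seed_connectivity(C2, seed)
  stopifnot(identical(names(r1), names(r2)))
  ct <- compare_edge_correlations(r1, C1$n_subjects, r2, C2$n_subjects)
  data.frame(region = names(r1), r_group1 = as.vector(r1),
             r_group2 = as.vector(r2), z = as.vector(ct$z),
             p = as.vector(ct$p), q = fdr_adjust(ct$p),
             row.names = NULL, stringsAsFactors = FALSE)
}
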