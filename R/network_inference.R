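# AUC over the sparsity sweep of each global metric, for one group's SUV.
group_global_auc <- function(suv, sparsities, rank_by = "signed") {
  curves <- global_metric_curves(correlation_matrix(suv), sparsities, rank_by)
  apply(curves, 2L, auc_over_sparsity, sparsities = sparsities)
}

#' Observed group difference in a network metric's sparsity AUC
#'
#' Builds each group's metabolic connectivity matrix, thresholds it across
#' the sparsity sweep, computes the metric per sparsity, and returns the
#' difference of the AUC summaries (first group minus second).
#'
#' @param suv_a,suv_b Subjects x regions SUV matrices for the two groups.
#' @param metric One of `"Cp"`, `"Lp"`, `"Eglob"`, `"Eloc"`.
#' @param sparsities Sparsity grid (default [sparsity_grid()]).
#' @param rank_by Edge ranking convention.
#' @return Scalar observed difference `AUC(a) - AUC(b)`.
#' @export
group_metric_difference <- function(suv_a, suv_b, metric = "Lp",
                                    sparsities = sparsity_grid(),
                                    rank_by = "signed") {
  metric <- match.arg(metric, c("Cp", "Lp", "Eglob", "Eloc"))
  a <- group_global_auc(suv_a, sparsities, rank_by)[metric]
  b <- group_global_auc(suv_b, sparsities, rank_by)[metric]
  unname(a - b)
}

#' Permutation test for group differences in global network metrics
#'
#' Non-parametric inference by random relabelling of group membership
#' (group sizes preserved): each relabelling rebuilds both group networks
#' across the sparsity sweep and recomputes the metric AUC difference. The
#' empirical two-tailed p-value uses the add-one convention
#' `p = (1 + #\{|null| >= |observed|\}) / (1 + n_perm)`, so p is never zero.
#' All requested metrics share the same relabellings.
#'
#' @param suv Subjects x regions SUV matrix (both groups).
#' @param group Two-level factor; observed difference is first level minus
#'   second.
#' @param metrics Global metrics to test (default all four).
#' @param n_perm Number of relabellings (default 5000).
#' @param rng_seed Integer seed for the relabelling stream.
#' @param sparsities Sparsity grid.
#' @param rank_by Edge ranking convention.
#' @return List of class `permutation_result_set`: per metric, a list with
#'   `metric`, `observed`, `null` (n_perm differences), `p`, `n_perm`,
#'   `rng_seed`.
#' @export
permutation_test <- function(suv, group, metrics = c("Cp", "Lp", "Eglob", "Eloc"),
                             n_perm = 5000L, rng_seed = 1L,
                             sparsities = sparsity_grid(), rank_by = "signed") {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("exactly two group labels required", call. = FALSE)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  metrics <- match.arg(metrics, c("Cp", "Lp", "Eglob", "Eloc"), several.ok = TRUE)
  n <- nrow(suv)
  lev <- levels(group)
  if (n_perm > choose(n, sum(group == lev[1L]))) {
    warning("n_perm exceeds the number of distinct relabellings; ",
            "sampling with replacement retained", call. = FALSE)
  }
  diff_for <- function(g) {
    a <- group_global_auc(suv[g == lev[1L], , drop = FALSE], sparsities, rank_by)
    b <- group_global_auc(suv[g == lev[2L], , drop = FALSE], sparsities, rank_by)
    (a - b)[metrics]
  }
  observed <- diff_for(group)
  set.seed(rng_seed)
  null <- vapply(seq_len(n_perm), function(b) diff_for(sample(group)),
                 numeric(length(metrics)))
  null <- matrix(null, nrow = length(metrics))
  out <- lapply(seq_along(metrics), function(k) {
    nk <- null[k, ]
    list(metric = metrics[k], observed = unname(observed[k]), null = nk,
         p = (1 + sum(abs(nk) >= abs(observed[k]))) / (1 + n_perm),
         n_perm = n_perm, rng_seed = rng_seed)
  })
  names(out) <- metrics
  class(out) <- "permutation_result_set"
  out
}

#' @export
print.permutation_result_set <- function(x, ...) {
  cat("Permutation tests (", x[[1L]]$n_perm, " relabellings):\n", sep = "")
  for (r in x) {
    cat(sprintf("  %-6s observed = %+0.5f, p = %0.4f\n",
                r$metric, r$observed, r$p))
  }
  invisible(x)
}

#' Per-node permutation tests on a nodal network metric
#'
#' One permutation test per region on the sparsity AUC of a nodal metric
#' (degree, betweenness or nodal efficiency), with Benjamini-Hochberg FDR
#' across regions. All regions share the same relabellings (preserving the
#' cross-region dependence structure of the null for the FDR step).
#'
#' @inheritParams permutation_test
#' @param metric One of `"degree"`, `"betweenness"`, `"efficiency"`.
#' @return Data frame with `region`, `observed` (AUC difference, first
#'   group minus second), `p`, `q`; attributes `n_perm` and `rng_seed`.
#' @export
nodal_permutation_tests <- function(suv, group,
                                    metric = c("degree", "betweenness", "efficiency"),
                                    n_perm = 5000L, rng_seed = 1L,
                                    sparsities = sparsity_grid(),
                                    rank_by = "signed") {
  metric <- match.arg(metric)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("exactly two group labels required", call. = FALSE)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  lev <- levels(group)
  nodal_auc <- function(suv_grp) {
    curves <- nodal_metric_curves(correlation_matrix(suv_grp), metric,
                                  sparsities, rank_by)
    apply(curves, 1L, auc_over_sparsity, sparsities = sparsities)
  }
  diff_for <- function(g) {
    nodal_auc(suv[g == lev[1L], , drop = FALSE]) -
      nodal_auc(suv[g == lev[2L], , drop = FALSE])
  }
  observed <- diff_for(group)
  set.seed(rng_seed)
  null <- vapply(seq_len(n_perm), function(b) diff_for(sample(group)),
                 numeric(ncol(suv)))
  null <- matrix(null, nrow = ncol(suv))
  exceed <- rowSums(abs(null) >= abs(observed))
  p <- (1 + exceed) / (1 + n_perm)
  out <- data.frame(region = colnames(suv), observed = unname(observed),
                    p = p, q = fdr_adjust(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  attr(out, "rng_seed") <- rng_seed
  attr(out, "metric") <- metric
  out
}
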