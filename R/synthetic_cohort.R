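#' Repair a symmetric matrix to the nearest positive semidefinite correlation matrix
#'
#' Eigenvalue clipping followed by rescaling to unit diagonal, iterated until
#' the smallest eigenvalue is above `-tol`. This is the light-weight repair
#' used after planting target correlations into a base matrix; for matrices
#' that are already positive semidefinite it returns the input unchanged.
#'
#' @param R Symmetric matrix with unit diagonal.
#' @param tol Eigenvalue tolerance; the result has min eigenvalue `>= -tol`.
#' @param max_iter Maximum clip/rescale iterations.
#' @return A symmetric unit-diagonal matrix with min eigenvalue `>= -tol`.
#' @export
nearest_correlation <- function(R, tol = 1e-8, max_iter = 100L) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (max(abs(R - t(R))) > 1e-10) stop("matrix is not symmetric", call. = FALSE)
  dn <- dimnames(R)
  X <- (R + t(R)) / 2
  for (it in seq_len(max_iter)) {
    e <- eigen(X, symmetric = TRUE)
    if (min(e$values) >= -tol) break
    v <- pmax(e$values, 0)
    X <- e$vectors %*% (v * t(e$vectors))
    d <- diag(X)
    if (any(d <= 0)) stop("degenerate diagonal during correlation repair", call. = FALSE)
    s <- 1 / sqrt(d)
    X <- X * tcrossprod(s)
    X <- (X + t(X)) / 2
    diag(X) <- 1
  }
  if (min(eigen(X, symmetric = TRUE, only.values = TRUE)$values) < -tol) {
    stop("correlation repair did not converge", call. = FALSE)
  }
  dimnames(X) <- dn
  X
}

#' Default base inter-regional correlation structure
#'
#' Smoothly structured coupling that decays with index distance,
#' `r_ij = 0.6^(1 + |i - j| / 10)`, floored at 0.2 for distant pairs, with
#' unit diagonal, repaired to positive semidefiniteness. Mimics the broadly
#' positive, spatially structured coupling of inter-regional metabolic
#' correlation matrices.
#'
#' @param n_rois Number of regions (default 90).
#' @return `n_rois` x `n_rois` correlation matrix.
#' @export
default_base_correlation <- function(n_rois = 90L) {
  d <- abs(outer(seq_len(n_rois), seq_len(n_rois), "-"))
  R <- pmax(0.6^(1 + d / 10), 0.2)
  diag(R) <- 1
  nearest_correlation(R)
}

#' Plant target correlations on named entries of a correlation matrix
#'
#' Sets the requested off-diagonal entries to their target values and repairs
#' the result to the nearest positive semidefinite correlation matrix
#' (eigenvalue clipping plus diagonal rescaling). When the planted matrix is
#' already positive semidefinite the targets are hit exactly; otherwise the
#' repair perturbs all entries slightly (typically by well under 0.01 for
#' mild plants on well-conditioned matrices).
#'
#' @param C Correlation matrix (symmetric, unit diagonal).
#' @param edges Data frame with columns `i`, `j` (indices or region names
#'   resolved against `rownames(C)`) and `r` (target correlation,
#'   `|r| < 1`). A zero-row data frame (or `NULL`) returns `C` unchanged.
#' @return Correlation matrix with planted entries.
#' @export
plant_edge_correlation <- function(C, edges) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (is.null(edges) || nrow(edges) == 0L) return(C)
  stopifnot(all(c("i", "j", "r") %in% names(edges)))
  resolve <- function(x) {
    if (is.character(x)) match(x, rownames(C)) else as.integer(x)
  }
  ii <- resolve(edges$i); jj <- resolve(edges$j)
  if (anyNA(ii) || anyNA(jj)) stop("unresolved region in planted edges", call. = FALSE)
  if (any(ii == jj)) stop("cannot plant a diagonal entry", call. = FALSE)
  if (any(abs(edges$r) >= 1)) {
    stop("planted correlations must satisfy |r| < 1", call. = FALSE)
  }
  X <- C
  for (k in seq_along(ii)) {
    X[ii[k], jj[k]] <- X[jj[k], ii[k]] <- edges$r[k]
  }
  nearest_correlation(X)
}

#' Demographic 2x2 count defaults emulating a lacunar-stroke case-control table
#'
#' Per-variable counts of trait-positive subjects in the patient (LS) and
#' control (HC) groups, for 70 subjects per group.
#'
#' @return Named list; each element is `c(ls = ..., hc = ...)`.
#' @export
default_demographics_counts <- function() {
  list(
    male          = c(ls = 52, hc = 42),
    hypertension  = c(ls = 23, hc = 13),
    hyperglycemia = c(ls = 10, hc = 6),
    hyperlipidemia = c(ls = 14, hc = 20),
    smoking       = c(ls = 10, hc = 1),
    drinking      = c(ls = 6,  hc = 0)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the two-group study the generator emulates: a patient group (LS)
#' and a control group (HC) of normalized SUV profiles over `n_rois` regions,
#' with a planted mean shift at a seed region in the LS group, planted
#' decorrelation of named seed--target edges in the LS group, peripheral
#' biomarkers coupled to the seed-region SUV in the LS group, and exact
#' demographic contingency counts.
#'
#' @param n_per_group Subjects per group (default 70).
#' @param n_rois Number of regions (default 90).
#' @param region_names Region names; defaults to [aal90_regions()] when
#'   `n_rois == 90`, else `"ROI_1"`, ....
#' @param base_correlation_matrix Base inter-regional correlation structure;
#'   defaults to [default_base_correlation()].
#' @param seed_roi Seed region carrying the planted mean shift (default
#'   `"Postcentral_R"` for the 90-region atlas, else the first region).
#' @param mean_shift_delta SUV-units shift added to the LS seed-region mean
#'   (default 0.05 = 0.5 x the default regional SD).
#' @param suv_sd Regional SUV standard deviation (default 0.1).
#' @param decorrelated_edges Data frame with columns `region_a`, `region_b`,
#'   `base_r` (planted into both groups) and `target_r` (LS-group value);
#'   defaults to the four seed--target edges reduced from 0.6 to 0.2.
#' @param biomarker_effects Data frame with columns `name`, `r` (target
#'   correlation with seed SUV in the LS group), `mean`, `sd`; defaults to
#'   AST (r = -0.277, 25 +/- 8 U/L) and PT (r = +0.256, 12 +/- 1 s).
#' @param demographics_counts Named list of `c(ls=, hc=)` trait counts;
#'   defaults to [default_demographics_counts()] (stated for 70 per group,
#'   scaled proportionally for other group sizes).
#' @param rng_seed Root seed; every random stream is derived from it.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 70L,
                          n_rois = 90L,
                          region_names = NULL,
                          base_correlation_matrix = NULL,
                          seed_roi = NULL,
                          mean_shift_delta = 0.05,
                          suv_sd = 0.1,
                          decorrelated_edges = NULL,
                          biomarker_effects = NULL,
                          demographics_counts = NULL,
                          rng_seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  n_rois <- as.integer(n_rois)
  if (n_per_group < 3L) stop("n_per_group must be >= 3", call. = FALSE)
  if (is.null(region_names)) {
    region_names <- if (n_rois == 90L) aal90_regions() else paste0("ROI_", seq_len(n_rois))
  }
  stopifnot(length(region_names) == n_rois)
  if (is.null(seed_roi)) {
    seed_roi <- if (n_rois == 90L) "Postcentral_R" else region_names[1L]
  }
  if (is.null(demographics_counts)) {
    # table defaults are stated for 70 per group; scale proportionally
    demographics_counts <- lapply(default_demographics_counts(), function(cnt) {
      pmin(round(cnt * n_per_group / 70), n_per_group)
    })
  }
  if (is.null(base_correlation_matrix)) {
    base_correlation_matrix <- default_base_correlation(n_rois)
  }
  stopifnot(nrow(base_correlation_matrix) == n_rois)
  dimnames(base_correlation_matrix) <- list(region_names, region_names)
  if (is.null(decorrelated_edges) && seed_roi == "Postcentral_R" && n_rois == 90L) {
    decorrelated_edges <- data.frame(
      region_a = "Postcentral_R",
      region_b = c("Caudate_R", "Amygdala_L", "Hippocampus_L", "SupraMarginal_L"),
      base_r = 0.6, target_r = 0.2,
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(decorrelated_edges)) {
    stopifnot(all(c("region_a", "region_b", "target_r") %in% names(decorrelated_edges)))
    if (is.null(decorrelated_edges$base_r)) decorrelated_edges$base_r <- NA_real_
    if (any(abs(decorrelated_edges$target_r) >= 1) ||
        any(abs(decorrelated_edges$base_r) >= 1, na.rm = TRUE)) {
      stop("edge correlations must satisfy |r| < 1", call. = FALSE)
    }
  }
  if (is.null(biomarker_effects)) {
    biomarker_effects <- data.frame(
      name = c("AST", "PT"), r = c(-0.277, 0.256),
      mean = c(25, 12), sd = c(8, 1), stringsAsFactors = FALSE
    )
  }
  match_region(seed_roi, region_names)
  structure(list(
    n_per_group = n_per_group, n_rois = n_rois, region_names = region_names,
    base_correlation_matrix = base_correlation_matrix, seed_roi = seed_roi,
    mean_shift_delta = mean_shift_delta, suv_sd = suv_sd,
    decorrelated_edges = decorrelated_edges,
    biomarker_effects = biomarker_effects,
    demographics_counts = demographics_counts,
    rng_seed = as.integer(rng_seed)
  ), class = "cohort_config")
}

# Derive named per-component integer seeds from one root seed, so components
# can be regenerated independently and the manifest records every stream.
derive_stream_seeds <- function(root_seed, streams) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(root_seed)
  setNames(sample.int(.Machine$integer.max - 1L, length(streams)), streams)
}

#' Generate demographic 2x2 contingency tables
#'
#' Builds one 2x2 table per configured variable with exactly the configured
#' trait counts (rows = group LS/HC, columns = trait yes/no). With the
#' default configuration this reproduces the study-style case-control table
#' (e.g. smoking 10/70 vs 1/70).
#'
#' @param config A [cohort_config()].
#' @return Named list of 2x2 integer matrices.
#' @export
generate_demographics <- function(config = cohort_config()) {
  n <- config$n_per_group
  lapply(config$demographics_counts, function(cnt) {
    if (any(cnt < 0)) stop("demographic counts must be non-negative", call. = FALSE)
    if (any(cnt > n)) stop("demographic counts cannot exceed n_per_group", call. = FALSE)
    m <- matrix(c(cnt[["ls"]], n - cnt[["ls"]], cnt[["hc"]], n - cnt[["hc"]]),
                nrow = 2, byrow = TRUE,
                dimnames = list(group = c("LS", "HC"), trait = c("yes", "no")))
    storage.mode(m) <- "integer"
    m
  })
}

# Group-specific correlation matrices implied by a config: base_r planted in
# both groups, target_r only in LS.
cohort_correlations <- function(config) {
  R_hc <- config$base_correlation_matrix
  edges <- config$decorrelated_edges
  if (!is.null(edges) && any(!is.na(edges$base_r))) {
    base <- edges[!is.na(edges$base_r), ]
    R_hc <- plant_edge_correlation(
      R_hc, data.frame(i = base$region_a, j = base$region_b, r = base$base_r))
  }
  R_ls <- R_hc
  if (!is.null(edges) && nrow(edges)) {
    R_ls <- plant_edge_correlation(
      R_hc, data.frame(i = edges$region_a, j = edges$region_b, r = edges$target_r))
  }
  list(HC = R_hc, LS = R_ls)
}

#' Generate a synthetic two-group cohort of normalized SUV profiles
#'
#' Draws the control group from a multivariate Gaussian with the configured
#' base correlation structure and the patient (LS) group from the same
#' structure with the configured seed--target edges decorrelated and the
#' seed-region mean shifted by `mean_shift_delta`. Biomarkers are generated
#' by Gaussian-copula conditioning on the seed-region SUV in the LS group
#' (independent in HC). Ages, sex and BMI are drawn with mild group
#' differences; binary demographic traits match the configured counts
#' exactly. Fully reproducible from `rng_seed` via derived per-component
#' streams recorded in the result.
#'
#' @param config A [cohort_config()].
#' @return Object of class `cohort_dataset`: list with `suv` (subjects x
#'   ROIs matrix, LS rows first), `group` (factor LS/HC), `covariates`
#'   (age/sex/bmi data frame), `biomarkers` (data frame, LS rows coupled to
#'   seed SUV), `demographics` (per-subject 0/1 traits), `region_names`,
#'   `config`, and `stream_seeds`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  n <- config$n_per_group
  p <- config$n_rois
  streams <- derive_stream_seeds(config$rng_seed,
    c("suv_ls", "suv_hc", "biomarkers", "covariates", "demographics"))
  corrs <- cohort_correlations(config)
  seed_idx <- match_region(config$seed_roi, config$region_names)

  mu_hc <- rep(1, p)
  mu_ls <- mu_hc
  mu_ls[seed_idx] <- mu_ls[seed_idx] + config$mean_shift_delta
  sigma_hc <- corrs$HC * config$suv_sd^2
  sigma_ls <- corrs$LS * config$suv_sd^2
  min_eig <- min(eigen(sigma_ls, symmetric = TRUE, only.values = TRUE)$values)
  if (min_eig < -1e-8 * config$suv_sd^2) {
    stop("planted covariance is not positive semidefinite after repair", call. = FALSE)
  }

  set.seed(streams[["suv_ls"]])
  suv_ls <- MASS::mvrnorm(n, mu_ls, sigma_ls)
  set.seed(streams[["suv_hc"]])
  suv_hc <- MASS::mvrnorm(n, mu_hc, sigma_hc)
  suv <- rbind(suv_ls, suv_hc)
  colnames(suv) <- config$region_names
  rownames(suv) <- c(sprintf("LS%03d", seq_len(n)), sprintf("HC%03d", seq_len(n)))
  group <- factor(rep(c("LS", "HC"), each = n), levels = c("LS", "HC"))

  # Biomarkers: copula conditioning on standardized seed SUV in the LS group.
  set.seed(streams[["biomarkers"]])
  z_seed <- as.vector(scale(suv_ls[, seed_idx]))
  bm <- config$biomarker_effects
  biomarkers <- as.data.frame(setNames(lapply(seq_len(nrow(bm)), function(k) {
    r <- bm$r[k]
    z_ls <- r * z_seed + sqrt(1 - r^2) * rnorm(n)
    z_hc <- rnorm(n)
    bm$mean[k] + bm$sd[k] * c(z_ls, z_hc)
  }), bm$name))
  rownames(biomarkers) <- rownames(suv)

  set.seed(streams[["covariates"]])
  age <- c(rnorm(n, 54, 8), rnorm(n, 50, 6))
  bmi <- c(rnorm(n, 24.3, 2.5), rnorm(n, 23.5, 2.5))
  covariates <- data.frame(age = age, bmi = bmi, row.names = rownames(suv))

  set.seed(streams[["demographics"]])
  demo <- lapply(config$demographics_counts, function(cnt) {
    if (any(cnt < 0) || any(cnt > n)) {
      stop("demographic counts must lie in [0, n_per_group]", call. = FALSE)
    }
    yes_ls <- sample.int(n, cnt[["ls"]])
    yes_hc <- sample.int(n, cnt[["hc"]])
    c(as.integer(seq_len(n) %in% yes_ls), as.integer(seq_len(n) %in% yes_hc))
  })
  demographics <- as.data.frame(demo, row.names = rownames(suv))
  covariates$sex <- factor(ifelse(demographics$male == 1L, "M", "F"),
                           levels = c("F", "M"))

  structure(list(
    suv = suv, group = group, covariates = covariates,
    biomarkers = biomarkers, demographics = demographics,
    region_names = config$region_names, config = config,
    stream_seeds = streams
  ), class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("Synthetic SUV cohort:", nrow(x$suv), "subjects x", ncol(x$suv),
      "regions\n  groups:", paste(sprintf("%s=%d", levels(x$group),
      table(x$group)), collapse = ", "),
      "\n  seed region:", x$config$seed_roi,
      "(mean shift", x$config$mean_shift_delta, "SUV)\n")
  invisible(x)
}

#' Write a cohort dataset to a directory as TSV + YAML
#'
#' Writes `suv.tsv` (subjects x regions, header = region names),
#' `manifest.tsv` (subject, group, age, sex, BMI, biomarkers, traits) and
#' `config.yaml` (configuration echo including all derived stream seeds).
#'
#' @param dataset A `cohort_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  suv <- data.frame(subject = rownames(dataset$suv), dataset$suv,
                    check.names = FALSE)
  write.table(suv, file.path(dir, "suv.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- data.frame(subject = rownames(dataset$suv),
                         group = as.character(dataset$group),
                         dataset$covariates, dataset$biomarkers,
                         dataset$demographics, check.names = FALSE)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- dataset$config
  echo <- list(
    n_per_group = cfg$n_per_group, n_rois = cfg$n_rois,
    seed_roi = cfg$seed_roi, mean_shift_delta = cfg$mean_shift_delta,
    suv_sd = cfg$suv_sd, rng_seed = cfg$rng_seed,
    stream_seeds = as.list(dataset$stream_seeds)
  )
  yaml::write_yaml(echo, file.path(dir, "config.yaml"))
  invisible(dir)
}
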