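#' Configuration for an end-to-end pipeline run
#'
#' @param mode Input mode: `"synthetic"` (generate a cohort), `"roi_table"`
#'   (read `suv.tsv` + `manifest.tsv`), or `"nifti"` (per-subject uptake
#'   volumes plus an atlas).
#' @param cohort A [cohort_config()] (synthetic mode).
#' @param suv_path,manifest_path TSV paths (roi_table mode).
#' @param volume_paths,atlas Named NIfTI paths and [read_atlas()] result
#'   (nifti mode); group/covariates still come from `manifest_path`.
#' @param seed_region Seed region for connectivity analyses.
#' @param sparsities Sparsity grid (default 0.10-0.50 step 0.01).
#' @param n_perm Permutation count for network inference (default 5000).
#' @param n_null Rewired nulls per sparsity for small-world normalization.
#' @param alpha Significance level used in the summary (default 0.05).
#' @param rng_seed Root seed for every stochastic stage.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "roi_table", "nifti"),
                            cohort = cohort_config(),
                            suv_path = NULL, manifest_path = NULL,
                            volume_paths = NULL, atlas = NULL,
                            seed_region = "Postcentral_R",
                            sparsities = sparsity_grid(),
                            n_perm = 5000L, n_null = 100L, alpha = 0.05,
                            rng_seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  if (length(sparsities) < 2L || any(diff(sparsities) <= 0) ||
      min(sparsities) <= 0 || max(sparsities) >= 1) {
    stop("invalid sparsity grid: need 0 < min < max < 1, strictly increasing",
         call. = FALSE)
  }
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  if (mode == "roi_table" && (is.null(suv_path) || is.null(manifest_path))) {
    stop("roi_table mode requires suv_path and manifest_path", call. = FALSE)
  }
  if (mode == "nifti" && (is.null(volume_paths) || is.null(atlas) ||
                          is.null(manifest_path))) {
    stop("nifti mode requires volume_paths, atlas and manifest_path", call. = FALSE)
  }
  structure(list(mode = mode, cohort = cohort, suv_path = suv_path,
                 manifest_path = manifest_path, volume_paths = volume_paths,
                 atlas = atlas, seed_region = seed_region,
                 sparsities = sparsities, n_perm = as.integer(n_perm),
                 n_null = as.integer(n_null), alpha = alpha,
                 rng_seed = as.integer(rng_seed), out_dir = out_dir),
            class = "pipeline_config")
}

read_roi_table_inputs <- function(suv_path, manifest_path) {
  suv_tab <- read.table(suv_path, sep = "\t", header = TRUE,
                        check.names = FALSE, stringsAsFactors = FALSE)
  manifest <- read.table(manifest_path, sep = "\t", header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot("subject" %in% names(suv_tab), all(c("subject", "group") %in% names(manifest)))
  suv <- as.matrix(suv_tab[, setdiff(names(suv_tab), "subject"), drop = FALSE])
  rownames(suv) <- suv_tab$subject
  manifest <- manifest[match(rownames(suv), manifest$subject), ]
  covars <- manifest[, intersect(c("age", "sex", "bmi"), names(manifest)),
                     drop = FALSE]
  if ("sex" %in% names(covars)) covars$sex <- factor(covars$sex)
  bio <- manifest[, intersect(c("AST", "PT"), names(manifest)), drop = FALSE]
  list(suv = suv,
       group = factor(manifest$group, levels = unique(manifest$group)),
       covariates = covars,
       biomarkers = if (ncol(bio)) bio else NULL)
}

#' Run the full metabolic connectomics pipeline
#'
#' Executes cohort generation (or ingestion), covariate-adjusted regional
#' SUV comparisons, seed connectivity and edge tests with FDR, the sparsity
#' sweep with global/nodal graph metrics and small-world normalization,
#' permutation inference on global metric AUCs, and clinical statistics.
#' With `out_dir` set, all stage outputs are written as TSV plus a JSON
#' summary and a YAML run manifest. Re-running with the same configuration
#' and seed reproduces every numeric output.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `report_bundle` (list of all stage results).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log <- character(0)
  note <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log <<- c(log, msg)
  }

  note("stage: input (", config$mode, ")")
  if (config$mode == "synthetic") {
    cohort_cfg <- config$cohort
    cohort_cfg$rng_seed <- config$rng_seed
    dataset <- generate_cohort(cohort_cfg)
    suv <- dataset$suv
    group <- dataset$group
    covariates <- dataset$covariates
    biomarkers <- dataset$biomarkers
  } else {
    if (config$mode == "nifti") {
      suv <- suv_matrix_from_volumes(config$volume_paths, config$atlas)
      manifest <- read_roi_table_inputs_manifest(config$manifest_path, suv)
      group <- manifest$group; covariates <- manifest$covariates
      biomarkers <- manifest$biomarkers
    } else {
      inp <- read_roi_table_inputs(config$suv_path, config$manifest_path)
      suv <- inp$suv; group <- inp$group; covariates <- inp$covariates
      biomarkers <- inp$biomarkers
    }
    dataset <- NULL
  }
  lev <- levels(group)

  note("stage: regional covariate-adjusted comparison")
  regional <- covariate_adjusted_group_difference(suv, group, covariates)

  note("stage: connectivity + seed edge tests (seed ", config$seed_region, ")")
  C1 <- correlation_matrix(suv[group == lev[1L], , drop = FALSE], lev[1L])
  C2 <- correlation_matrix(suv[group == lev[2L], , drop = FALSE], lev[2L])
  edges <- seed_edge_tests(C1, C2, config$seed_region)

  note("stage: network sweep + global metrics")
  curves1 <- global_metric_curves(C1, config$sparsities)
  curves2 <- global_metric_curves(C2, config$sparsities)
  auc1 <- apply(curves1, 2L, auc_over_sparsity, sparsities = config$sparsities)
  auc2 <- apply(curves2, 2L, auc_over_sparsity, sparsities = config$sparsities)

  note("stage: small-world normalization (n_null = ", config$n_null, ")")
  mid_s <- config$sparsities[ceiling(length(config$sparsities) / 2)]
  sw <- lapply(setNames(list(C1, C2), lev), function(C) {
    small_world_metrics(threshold_by_sparsity(C, mid_s),
                        n_null = config$n_null, rng_seed = config$rng_seed)
  })

  note("stage: permutation inference (n_perm = ", config$n_perm, ")")
  perm <- permutation_test(suv, group, n_perm = config$n_perm,
                           rng_seed = config$rng_seed,
                           sparsities = config$sparsities)

  note("stage: clinical statistics")
  clinical <- if (!is.null(dataset)) demographics_tests(dataset) else NULL
  biomarker_cor <- NULL
  if (!is.null(biomarkers) && ncol(biomarkers)) {
    seed_vals <- suv[group == lev[1L], match_region(config$seed_region,
                                                   colnames(suv))]
    biomarker_cor <- do.call(rbind, lapply(names(biomarkers), function(b) {
      ct <- suv_biomarker_correlation(seed_vals,
                                      biomarkers[[b]][group == lev[1L]])
      data.frame(biomarker = b, r = ct$r, p = ct$p, n = ct$n,
                 stringsAsFactors = FALSE)
    }))
  }

  summary <- list(
    groups = as.list(setNames(as.integer(table(group)), lev)),
    seed_region = config$seed_region,
    top_regional = regional$region[which.min(regional$q)],
    regional_significant = regional$region[regional$q < config$alpha],
    edges_significant = edges$region[edges$q < config$alpha],
    global_auc = list(setNames(as.list(auc1), colnames(curves1)),
                      setNames(as.list(auc2), colnames(curves2))),
    permutation_p = lapply(perm, function(r)
      list(observed = r$observed, p = r$p, n_perm = r$n_perm,
           rng_seed = r$rng_seed)),
    small_world = lapply(sw, function(s)
      list(gamma = s$gamma, lambda = s$lambda, sigma = s$sigma)),
    alpha = config$alpha, rng_seed = config$rng_seed
  )
  names(summary$global_auc) <- lev

  bundle <- structure(list(
    dataset = dataset, suv = suv, group = group, regional = regional,
    connectivity = setNames(list(C1, C2), lev), edge_tests = edges,
    global_curves = setNames(list(curves1, curves2), lev),
    global_auc = setNames(list(auc1, auc2), lev), small_world = sw,
    permutation = perm, clinical = clinical, biomarker_cor = biomarker_cor,
    summary = summary, config = config, log = log
  ), class = "report_bundle")

  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir, t0)
  bundle
}

write_report_bundle <- function(bundle, dir, t0 = Sys.time()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) write.table(x, file.path(dir, name), sep = "\t",
                                       quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$dataset)) write_cohort(bundle$dataset, dir)
  tsv(bundle$regional, "regional_tests.tsv")
  tsv(bundle$edge_tests, "edge_tests.tsv")
  for (g in names(bundle$connectivity)) {
    write.table(bundle$connectivity[[g]]$r,
                file.path(dir, paste0("connectivity_", g, ".tsv")),
                sep = "\t", quote = FALSE)
  }
  gm <- do.call(rbind, lapply(names(bundle$global_curves), function(g) {
    data.frame(group = g, sparsity = bundle$config$sparsities,
               bundle$global_curves[[g]], row.names = NULL)
  }))
  tsv(gm, "global_metrics.tsv")
  pm <- do.call(rbind, lapply(bundle$permutation, function(r) {
    data.frame(metric = r$metric, observed = r$observed, p = r$p,
               n_perm = r$n_perm, rng_seed = r$rng_seed)
  }))
  tsv(pm, "permutation_results.tsv")
  if (!is.null(bundle$clinical)) tsv(bundle$clinical, "demographics_tests.tsv")
  if (!is.null(bundle$biomarker_cor)) tsv(bundle$biomarker_cor,
                                          "biomarker_correlations.tsv")
  jsonlite::write_json(bundle$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    mode = bundle$config$mode, rng_seed = bundle$config$rng_seed,
    n_perm = bundle$config$n_perm, n_null = bundle$config$n_null,
    sparsities = range(bundle$config$sparsities),
    seed_region = bundle$config$seed_region,
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("metaconn")),
    started = format(t0), finished = format(Sys.time()),
    log = bundle$log
  )
  yaml::write_yaml(manifest, file.path(dir, "run_manifest.yaml"))
  invisible(dir)
}

read_roi_table_inputs_manifest <- function(manifest_path, suv) {
  manifest <- read.table(manifest_path, sep = "\t", header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE)
  manifest <- manifest[match(rownames(suv), manifest$subject), ]
  covars <- manifest[, intersect(c("age", "sex", "bmi"), names(manifest)),
                     drop = FALSE]
  if ("sex" %in% names(covars)) covars$sex <- factor(covars$sex)
  bio <- manifest[, intersect(c("AST", "PT"), names(manifest)), drop = FALSE]
  list(group = factor(manifest$group, levels = unique(manifest$group)),
       covariates = covars, biomarkers = if (ncol(bio)) bio else NULL)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Metabolic connectomics report\n")
  cat("  subjects:", nrow(x$suv), "| regions:", ncol(x$suv), "\n")
  cat("  top regional difference:", x$summary$top_regional, "\n")
  cat("  seed edges with q <", x$summary$alpha, ":",
      length(x$summary$edges_significant), "\n")
  for (r in x$permutation) {
    cat(sprintf("  %-6s AUC diff %+0.4f (p = %0.4f)\n", r$metric,
                r$observed, r$p))
  }
  invisible(x)
}
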