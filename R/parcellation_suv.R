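#' Read an atlas label volume and its label table
#'
#' @param label_path Path to a NIfTI integer label volume (0 = background).
#' @param table_path Path to a TSV with columns `label` and `region_name`
#'   (one row per atlas region, conventionally 90).
#' @return List with `label_volume` (integer 3D array) and `label_table`.
#' @export
read_atlas <- function(label_path, table_path) {
  vol <- RNifti::readNifti(label_path)
  tab <- read.table(table_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  stopifnot(all(c("label", "region_name") %in% names(tab)))
  list(label_volume = array(as.integer(round(as.array(vol))), dim = dim(vol)),
       label_table = tab)
}

#' Mean uptake per atlas region
#'
#' Averages an uptake volume over the voxels of each atlas label; background
#' (label 0) is excluded. Every label in the atlas table must be present in
#' the label volume.
#'
#' @param uptake_volume 3D numeric array of tracer uptake.
#' @param atlas List with `label_volume` (same shape integer array) and
#'   `label_table` (data frame with `label`, `region_name`).
#' @return List with `roi_means` and `roi_volumes` (voxel counts), both
#'   named by region, in label-table order.
#' @export
aggregate_label_image <- function(uptake_volume, atlas) {
  lab <- as.vector(atlas$label_volume)
  up <- as.vector(uptake_volume)
  if (length(lab) != length(up)) {
    stop("uptake and label volumes have different shapes", call. = FALSE)
  }
  keep <- lab != 0L
  lab <- lab[keep]; up <- up[keep]
  labels <- atlas$label_table$label
  f <- factor(lab, levels = labels)
  missing <- labels[tabulate(f, nbins = length(labels)) == 0L]
  if (length(missing)) {
    stop("atlas labels with no voxels in the volume: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  roi_means <- as.vector(tapply(up, f, mean))
  roi_volumes <- as.vector(table(f))
  names(roi_means) <- names(roi_volumes) <- atlas$label_table$region_name
  list(roi_means = roi_means, roi_volumes = roi_volumes)
}

#' Normalize regional uptake to whole-brain-mean-one SUV ratios
#'
#' Divides each regional mean uptake by the subject's whole-brain mean
#' uptake, computed as the volume-weighted mean over the atlas regions
#' (cerebellum is absent from the 90-region parcellation and therefore does
#' not contribute). The resulting values are unitless ratios whose
#' volume-weighted mean is exactly 1.
#'
#' @param roi_means Regional mean uptake values.
#' @param roi_volumes Regional voxel counts (all `> 0`).
#' @return Object of class `suv_vector`: list with `values` and
#'   `roi_volumes`.
#' @export
normalize_suv <- function(roi_means, roi_volumes) {
  stopifnot(length(roi_means) == length(roi_volumes))
  if (any(roi_volumes <= 0)) stop("all ROI volumes must be positive", call. = FALSE)
  wb <- sum(roi_means * roi_volumes) / sum(roi_volumes)
  if (!is.finite(wb) || wb <= 0) {
    stop("whole-brain mean uptake must be positive", call. = FALSE)
  }
  structure(list(values = roi_means / wb, roi_volumes = roi_volumes),
            class = "suv_vector")
}

#' Covariate-adjusted regional group comparison
#'
#' Fits, per region, an ordinary least squares model
#' `SUV ~ group + covariates` and returns the group-term t statistic
#' (oriented first level minus second, i.e. patient minus control with
#' levels `c("LS","HC")`), its two-sided p-value and Benjamini-Hochberg
#' adjusted q across regions. With `covariates = NULL` the test reduces
#' exactly to the pooled-variance two-sample t-test.
#'
#' @param suv Subjects x regions matrix of normalized SUV.
#' @param group Factor with two levels (first level is the patient group).
#' @param covariates Data frame of per-subject covariates (numeric or
#'   factor; e.g. age, sex, BMI), or `NULL`.
#' @return Data frame with columns `region`, `t`, `p`, `q`; attribute
#'   `covariates` records the adjustment variables.
#' @export
covariate_adjusted_group_difference <- function(suv, group, covariates = NULL) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("group must have exactly two levels", call. = FALSE)
  if (min(table(group)) < 2L) stop("need >= 2 subjects per group", call. = FALSE)
  n <- nrow(suv)
  g <- as.integer(group == levels(group)[1L])  # 1 = patient group
  X <- cbind(`(Intercept)` = 1, group = g)
  if (!is.null(covariates)) {
    mm <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
    X <- cbind(X, mm)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("design matrix is rank deficient (a covariate is collinear with ",
         "the group indicator or another covariate)", call. = FALSE)
  }
  fit <- lm.fit(X, suv)
  res <- as.matrix(fit$residuals)
  df <- n - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtx_inv_gg <- chol2inv(qr.R(qrX))[2L, 2L]
  tval <- fit$coefficients["group", ] / sqrt(sigma2 * xtx_inv_gg)
  pval <- 2 * pt(-abs(tval), df)
  out <- data.frame(region = colnames(suv), t = as.vector(tval),
                    p = as.vector(pval), q = p.adjust(pval, "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "covariates") <- if (is.null(covariates)) character(0) else names(covariates)
  out
}

#' Build a subject x region SUV matrix from per-subject uptake volumes
#'
#' Convenience wrapper composing [aggregate_label_image()] and
#' [normalize_suv()] over a list of uptake volumes (or NIfTI paths).
#'
#' @param volumes Named list of 3D arrays or NIfTI file paths.
#' @param atlas Atlas as returned by [read_atlas()].
#' @return Subjects x regions matrix of normalized SUV.
#' @export
suv_matrix_from_volumes <- function(volumes, atlas) {
  rows <- lapply(volumes, function(v) {
    if (is.character(v)) v <- as.array(RNifti::readNifti(v))
    agg <- aggregate_label_image(v, atlas)
    normalize_suv(agg$roi_means, agg$roi_volumes)$values
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(volumes)
  out
}
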