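#' Pearson chi-square test for a 2x2 contingency table
#'
#' Uncorrected Pearson chi-square with 1 degree of freedom by default (the
#' form under which published case-control demographic statistics such as
#' smoking 10/70 vs 1/70 -> 7.992 are reproduced exactly); Yates continuity
#' correction available behind a flag.
#'
#' @param tab 2x2 matrix of counts (rows = group, columns = trait yes/no).
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return List with `statistic` and `p`.
#' @export
chi_square_2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L))
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(tab) == 0) stop("table is empty", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: a zero row or column margin", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value))
}

#' Two-sample t-test from summary statistics
#'
#' Independent-sample t-test computed from per-group mean, standard error
#' and sample size: `t = (mean1 - mean2) / sqrt(se1^2 + se2^2)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. Accepts
#' standard deviations by passing `se = sd / sqrt(n)`.
#'
#' @param mean1,se1,n1 Summary statistics for group 1.
#' @param mean2,se2,n2 Summary statistics for group 2.
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t_from_summary <- function(mean1, se1, n1, mean2, se2, n2) {
  if (se1 < 0 || se2 < 0) stop("standard errors must be non-negative", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("sample sizes must be >= 2", call. = FALSE)
  v <- se1^2 + se2^2
  if (v == 0) {
    if (mean1 == mean2) stop("undefined statistic: zero variance and equal means",
                             call. = FALSE)
    return(list(t = sign(mean1 - mean2) * Inf, df = NA_real_, p = 0))
  }
  t <- (mean1 - mean2) / sqrt(v)
  df <- v^2 / (se1^4 / (n1 - 1) + se2^4 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' Rank-sum U statistic with midranks for ties, a normal approximation with
#' tie-corrected variance, and a two-sided p-value. The z statistic is
#' exposed (as published non-parametric group comparisons report Z).
#'
#' @param x,y Numeric samples.
#' @return List with `U` (for sample `x`), `z`, `p`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) {
    warning("all values identical across both samples; p set to 1", call. = FALSE)
    return(list(U = U, z = 0, p = 1))
  }
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  list(U = U, z = z, p = 2 * pnorm(-abs(z)))
}

#' Correlation between seed-region SUV and a peripheral biomarker
#'
#' Pearson correlation with a two-sided t-based p-value, the analysis used
#' to relate regional metabolism to blood/liver parameters (e.g. AST, PT).
#'
#' @param suv_seed Per-subject seed-region SUV values.
#' @param biomarker Per-subject biomarker values (same length, `n >= 4`).
#' @return List with `r`, `p`, `n`.
#' @export
suv_biomarker_correlation <- function(suv_seed, biomarker) {
  stopifnot(length(suv_seed) == length(biomarker))
  keep <- is.finite(suv_seed) & is.finite(biomarker)
  suv_seed <- suv_seed[keep]; biomarker <- biomarker[keep]
  if (length(suv_seed) < 4L) stop("need >= 4 complete observations", call. = FALSE)
  if (sd(suv_seed) == 0 || sd(biomarker) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  ct <- cor.test(suv_seed, biomarker, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(suv_seed))
}

#' Demographic group comparisons for a cohort
#'
#' Chi-square tests on each binary trait's 2x2 table plus a Welch t-test on
#' age and a Mann-Whitney U test on BMI.
#'
#' @param dataset A `cohort_dataset` from [generate_cohort()].
#' @return Data frame with `variable`, `test`, `statistic`, `p`.
#' @export
demographics_tests <- function(dataset) {
  g <- dataset$group
  lev <- levels(g)
  rows <- lapply(names(dataset$demographics), function(v) {
    tab <- table(factor(g, levels = lev),
                 factor(dataset$demographics[[v]], levels = c(1, 0)))
    ct <- chi_square_2x2(tab)
    data.frame(variable = v, test = "chi-square", statistic = ct$statistic,
               p = ct$p, stringsAsFactors = FALSE)
  })
  age1 <- dataset$covariates$age[g == lev[1L]]
  age2 <- dataset$covariates$age[g == lev[2L]]
  tt <- two_sample_t_from_summary(mean(age1), sd(age1) / sqrt(length(age1)),
                                  length(age1), mean(age2),
                                  sd(age2) / sqrt(length(age2)), length(age2))
  mw <- mann_whitney_u(dataset$covariates$bmi[g == lev[1L]],
                       dataset$covariates$bmi[g == lev[2L]])
  rbind(do.call(rbind, rows),
        data.frame(variable = "age", test = "t", statistic = tt$t, p = tt$p,
                   stringsAsFactors = FALSE),
        data.frame(variable = "bmi", test = "mann-whitney", statistic = mw$z,
                   p = mw$p, stringsAsFactors = FALSE))
}
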