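test_that("planting correlations hits targets and preserves PSD", {
  C <- diag(5)
  expect_identical(plant_edge_correlation(C, NULL), C)
  expect_identical(plant_edge_correlation(C, data.frame(i = integer(),
                                                        j = integer(),
                                                        r = numeric())), C)

  planted <- plant_edge_correlation(C, data.frame(i = 1, j = 2, r = 0.6))
  expect_equal(planted[1, 2], 0.6, tolerance = 1e-6)
  expect_equal(planted, t(planted))
  expect_equal(diag(planted), rep(1, 5))
  # identity + one planted entry is already PSD: alternating-projection
  # oracle must agree that nothing needs repair
  oracle <- oracle_nearest_psd_corr({
    X <- C; X[1, 2] <- X[2, 1] <- 0.6; X
  })
  expect_equal(planted, oracle, tolerance = 1e-6, ignore_attr = TRUE)

  # an aggressively inconsistent plant still comes back PSD
  R <- matrix(0.9, 4, 4); diag(R) <- 1
  bad <- plant_edge_correlation(R, data.frame(i = c(1, 1), j = c(2, 3),
                                              r = c(-0.9, -0.9)))
  expect_gte(min(eigen(bad, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  expect_equal(diag(bad), rep(1, 4))

  expect_error(plant_edge_correlation(C, data.frame(i = 1, j = 2, r = 1)),
               "\\|r\\| < 1")
  expect_error(plant_edge_correlation(C, data.frame(i = 2, j = 2, r = 0.5)),
               "diagonal")
})

test_that("default base correlation is a valid correlation matrix", {
  for (n in c(10L, 90L)) {
    R <- default_base_correlation(n)
    expect_equal(diag(R), rep(1, n))
    expect_equal(R, t(R))
    expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    expect_true(all(R >= -1 & R <= 1))
  }
})

test_that("cohort generation is byte-identical under a fixed seed", {
  cfg <- cohort_config(n_per_group = 10L, n_rois = 20L, rng_seed = 99L)
  d1 <- generate_cohort(cfg)
  d2 <- generate_cohort(cfg)
  expect_identical(d1$suv, d2$suv)
  expect_identical(d1$biomarkers, d2$biomarkers)
  expect_identical(d1$covariates, d2$covariates)
  expect_identical(d1$demographics, d2$demographics)
  d3 <- generate_cohort(cohort_config(n_per_group = 10L, n_rois = 20L,
                                      rng_seed = 100L))
  expect_false(identical(d1$suv, d3$suv))
})

test_that("cohort dataset satisfies its structural invariants", {
  cfg <- cohort_config(n_per_group = 12L, rng_seed = 5L)
  d <- generate_cohort(cfg)
  expect_equal(nrow(d$suv), 24L)
  expect_equal(ncol(d$suv), 90L)
  expect_identical(colnames(d$suv), aal90_regions())
  expect_false(anyNA(d$suv))
  expect_equal(as.vector(table(d$group)), c(12L, 12L))
})

test_that("empirical moments converge to configured targets at large n", {
  cfg <- cohort_config(n_per_group = 2000L, n_rois = 30L,
                       region_names = paste0("R", 1:30),
                       seed_roi = "R5", mean_shift_delta = 0.3,
                       decorrelated_edges = data.frame(
                         region_a = "R5", region_b = "R12",
                         base_r = 0.6, target_r = 0.2),
                       rng_seed = 11L)
  d <- generate_cohort(cfg)
  ls <- d$suv[d$group == "LS", ]
  hc <- d$suv[d$group == "HC", ]
  expect_lt(abs(mean(ls[, "R5"]) - mean(hc[, "R5"]) - 0.3), 0.02)
  expect_lt(abs(cor(hc[, "R5"], hc[, "R12"]) - 0.6), 0.05)
  expect_lt(abs(cor(ls[, "R5"], ls[, "R12"]) - 0.2), 0.05)
})

test_that("biomarker couplings reach their target correlations at large n", {
  cfg <- cohort_config(n_per_group = 2000L, n_rois = 10L,
                       region_names = paste0("R", 1:10), seed_roi = "R3",
                       decorrelated_edges = NULL, rng_seed = 21L)
  d <- generate_cohort(cfg)
  ls <- d$group == "LS"
  expect_lt(abs(cor(d$suv[ls, "R3"], d$biomarkers$AST[ls]) - (-0.277)), 0.05)
  expect_lt(abs(cor(d$suv[ls, "R3"], d$biomarkers$PT[ls]) - 0.256), 0.05)
  # controls: no coupling
  expect_lt(abs(cor(d$suv[!ls, "R3"], d$biomarkers$AST[!ls])), 0.08)
})

test_that("demographic tables reproduce the configured case-control counts", {
  tabs <- generate_demographics(cohort_config())
  expect_equal(unname(tabs$smoking), matrix(c(10L, 60L, 1L, 69L), 2,
                                            byrow = TRUE))
  expect_equal(unname(tabs$hypertension), matrix(c(23L, 47L, 13L, 57L), 2,
                                                 byrow = TRUE))
  expect_equal(unname(tabs$male), matrix(c(52L, 18L, 42L, 28L), 2,
                                         byrow = TRUE))
  # degenerate zero-count variable is accepted
  cfg0 <- cohort_config(demographics_counts = list(rare = c(ls = 0, hc = 0)))
  expect_equal(unname(generate_demographics(cfg0)$rare),
               matrix(c(0L, 70L, 0L, 70L), 2, byrow = TRUE))
  expect_error(generate_demographics(
    cohort_config(demographics_counts = list(x = c(ls = -1, hc = 0)))),
    "non-negative")
  expect_error(generate_demographics(
    cohort_config(demographics_counts = list(x = c(ls = 80, hc = 0)))),
    "exceed")
  # per-subject traits in the generated cohort match the same counts
  d <- generate_cohort(cohort_config(rng_seed = 2L))
  expect_equal(sum(d$demographics$smoking[d$group == "LS"]), 10L)
  expect_equal(sum(d$demographics$smoking[d$group == "HC"]), 1L)
})

test_that("planted effects are recovered at rates frozen from the power oracle", {
  # Regression thresholds frozen from an independent 200-replicate power
  # simulation at the planted-effect design (seed-top rate 0.655, >=1-edge
  # FDR recovery rate 0.49); bounds sit ~3 binomial SDs below those rates.
  n_rep <- 50
  seed_top <- 0
  edge_any <- 0
  for (rep in seq_len(n_rep)) {
    d <- generate_cohort(cohort_config(rng_seed = 1000L + rep))
    reg <- covariate_adjusted_group_difference(d$suv, d$group, d$covariates)
    seed_top <- seed_top + (reg$region[which.max(abs(reg$t))] == "Postcentral_R")
    et <- seed_edge_tests(
      correlation_matrix(d$suv[d$group == "LS", ], "LS"),
      correlation_matrix(d$suv[d$group == "HC", ], "HC"), "Postcentral_R")
    planted <- c("Caudate_R", "Amygdala_L", "Hippocampus_L", "SupraMarginal_L")
    edge_any <- edge_any + (sum(et$q[et$region %in% planted] < 0.05) >= 1)
  }
  expect_gte(seed_top / n_rep, 0.45)
  expect_gte(edge_any / n_rep, 0.30)
})

test_that("cohort writer round-trips through TSV", {
  d <- generate_cohort(cohort_config(n_per_group = 5L, n_rois = 8L,
                                     region_names = paste0("R", 1:8),
                                     seed_roi = "R2",
                                     decorrelated_edges = NULL,
                                     rng_seed = 3L))
  dir <- withr::local_tempdir()
  write_cohort(d, dir)
  expect_true(all(file.exists(file.path(dir, c("suv.tsv", "manifest.tsv",
                                               "config.yaml")))))
  back <- read.table(file.path(dir, "suv.tsv"), sep = "\t", header = TRUE,
                     check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), d$suv, tolerance = 1e-12,
               ignore_attr = TRUE)
})
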