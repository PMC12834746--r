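# metaconn

Group-level metabolic connectivity and brain-network analysis for
atlas-parcellated FDG-PET, with a synthetic cohort generator that makes the
entire pipeline testable without patient data.

## Who this is for

Studies of cerebral glucose metabolism in case-control designs (e.g. lacunar
stroke patients versus healthy controls) commonly analyse three layers of
^18F-FDG-PET information:

1. **Regional uptake.** Each subject's PET volume is parcellated into the 90
   cerebral regions of the Automated Anatomical Labeling (AAL) atlas and
   each region's mean uptake is divided by the subject's whole-brain mean,
   giving a unitless standardized uptake value (SUV) ratio whose
   volume-weighted mean is exactly 1. Regional group differences are tested
   with per-region OLS models `SUV ~ group + age + sex + BMI` and
   Benjamini–Hochberg FDR across regions.
2. **Metabolic connectivity.** Within each group, the Pearson correlation
   across subjects between the SUVs of two regions defines the group-level
   metabolic connectivity `r_ij`. Seed-based edges are compared between
   groups with the Fisher r-to-z test
   `z = (atanh(r1) − atanh(r2)) / sqrt(1/(n1−3) + 1/(n2−3))`
   (a subject-level permutation alternative is provided), with FDR control
   over the seed's 89 edges.
3. **Network topology.** Each group's connectivity matrix is thresholded
   across a sparsity sweep (0.10–0.50, step 0.01; sparsity = fraction of the
   4,005 possible edges retained) into undirected binary graphs. Per
   sparsity the package computes the clustering coefficient Cp,
   characteristic path length Lp, global and local efficiency
   Eglob/Eloc, nodal degree, betweenness and efficiency, and the
   small-world indices γ = Cp/⟨Cp_rand⟩, λ = Lp/⟨Lp_rand⟩, σ = γ/λ against
   degree-preserving (Maslov–Sneppen) rewired nulls. Group inference uses
   non-parametric permutation tests on the area under each metric's
   sparsity curve (group labels relabelled, sizes preserved, add-one
   empirical p), plus FDR over nodal families.

Because each group yields a *single* network per sparsity, permutation over
group relabellings is the only distribution-free route to inference — the
package wires that in end to end.

The synthetic cohort generator (`generate_cohort()`) emulates the
statistical structure such a study assumes: two groups of multivariate
Gaussian SUV profiles with a planted mean shift at a seed region (default:
right postcentral gyrus), planted decorrelation of named seed–target edges,
biomarkers coupled to seed SUV by Gaussian-copula conditioning (AST
negative, PT positive), and demographic 2×2 tables with exact configured
counts.

## Worked example

```r
library(metaconn)

cfg <- pipeline_config(
  cohort      = cohort_config(),          # 70/group, 90 regions, planted effects
  sparsities  = sparsity_grid(step = 0.02),
  n_perm      = 500, n_null = 50, rng_seed = 20260926
)
bundle <- run_pipeline(cfg)               # a few minutes
print(bundle)
```

```
Metabolic connectomics report
  subjects: 140 | regions: 90
  top regional difference: Postcentral_R
  seed edges with q < 0.05 : 0
  Cp     AUC diff -0.0284 (p = 0.0060)
  Lp     AUC diff -0.1106 (p = 0.0040)
  Eglob  AUC diff +0.0100 (p = 0.0040)
  Eloc   AUC diff -0.0140 (p = 0.0200)
```

The planted +0.5 SD uptake shift is recovered as the top regional
difference (`Postcentral_R`, t = 3.96, q = 0.011), and the planted edge
decorrelations appear as the smallest edge-test p-values
(supramarginal/caudate/amygdala edges, p ≈ 0.005–0.014) although at this
effect size they do not pass the q < 0.05 edge threshold in every
replicate — see the vignette's power discussion. The `AUC diff` lines are
observed LS − HC differences in the area under each global metric's
sparsity curve with their permutation p-values; small-world indices and
biomarker correlations are in `bundle$summary` and `bundle$biomarker_cor`.

Individual stages are exported directly: `normalize_suv()`,
`correlation_matrix()`, `seed_edge_tests()`, `threshold_by_sparsity()`,
`global_graph_metrics()`, `small_world_metrics()`, `permutation_test()`,
`chi_square_2x2()`, and friends. A thin command-line runner ships at
`inst/exec/run_pipeline.R`.

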