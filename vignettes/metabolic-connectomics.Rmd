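---
title: "Metabolic connectomics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic connectomics: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaconn)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the conventions adopted where the field's
practice varies, what the synthetic generator does and does not emulate,
and the numerical choices that matter for reproducibility.

## 1. The analysis model

### SUV normalization

Regional tracer uptake is made comparable across subjects by dividing each
region's mean uptake by the subject's whole-brain mean, defined here as the
volume-weighted mean over the 90 atlas regions (the parcellation excludes
the cerebellum, so the cerebellum does not contribute to the normalizing
mean; `normalize_suv()` accepts any region set, so users who prefer a
cerebellum-inclusive denominator can pass it explicitly). The resulting
SUV ratios are unitless with volume-weighted mean exactly 1, and the
aggregate-then-normalize composition is invariant to any global rescaling
of the uptake volume — injected dose and scanner gain cancel.

The regional group comparison is an ordinary least squares model per
region, `SUV ~ group + age + sex + BMI`, with the group-term t statistic
(oriented patient − control), two-sided p, and Benjamini–Hochberg q across
the 90 regions. This ROI-level GLM is the package's deliberate replacement
for voxel-wise SPM mapping: every downstream analysis (connectivity,
networks) operates on the parcellation, so regional inference is kept at
the same granularity. With `covariates = NULL` the model reduces exactly to
the pooled-variance two-sample t-test, which the test suite verifies; with
random zero-effect covariates the statistic moves only through the lost
degrees of freedom and finite-sample non-orthogonality, which is why exact
equality is asserted only for the reduced model. Sex enters as a 0/1
indicator; no interactions.

### Metabolic connectivity

Connectivity is a *group-level* construct: the Pearson correlation across
the subjects of one group between the SUVs of two regions. It captures
coordinated between-subject variation in regional metabolism, not
within-subject dynamics; there is no single-subject connectivity here by
design. Zero-variance regions (possible with degenerate synthetic configs
or masked data) map to r = 0 with a warning rather than NaN, keeping the
pipeline total; the warning is the audit trail.

Edge differences between groups use the Fisher r-to-z two-sample statistic.
The field rarely names its edge test; Fisher z is the standard
two-independent-samples choice, is deterministic and fast, and the package
verifies it against a subject-level permutation test
(`edge_permutation_test()`), which is also exposed for users who prefer
distribution-free edge inference. The FDR family defaults to the 89 seed
edges, matching a seed-based analysis; testing all 4,005 edges is a
configuration choice, not a different code path.

### Binary networks and graph metrics

At sparsity `s`, the `K = round-half-up(s · 4005)` strongest edges are kept
and binarized. Two conventions are fixed for cross-platform determinism:
rounding of K is half-up, and rank ties break lexicographically by (i, j).
Edges are ranked by **signed** correlation by default — metabolic
covariance networks are conventionally built on positive coupling — with
`rank_by = "absolute"` available.

Global metrics: clustering coefficient Cp (mean local clustering, 0 for
degree < 2), characteristic path length Lp, global efficiency Eglob (mean
inverse distance, 1/∞ = 0), local efficiency Eloc (mean over nodes of the
neighbour-subgraph global efficiency). Nodal metrics: degree, betweenness
(Brandes convention, undirected, unnormalized), nodal efficiency.

**Disconnected graphs.** At low sparsity the thresholded graph can be
disconnected. Lp is computed over *connected ordered pairs only* — the
common toolbox convention, which keeps Lp finite; whether published
analyses use this or a harmonic-mean variant is usually unstated, so both
perspectives are available (the harmonic view is exactly Eglob). For
connected graphs Eglob ≥ 1/Lp (Jensen), which the suite asserts on random
graphs.

**Implementation note.** Metrics are computed with dense adjacency-matrix
algebra (triangle counts from A³ row sums, all-pairs distances from boolean
matrix powers), which for ≤ 90-node graphs is substantially faster than
per-graph conversion into a graph library and matters inside permutation
loops; betweenness and degree-preserving rewiring use igraph. All metrics
are validated against independent brute-force oracles (queue-based BFS,
explicit triangle enumeration, shortest-path counting) to 1e−12 on random
graphs and against hand-computed closed forms on K4, P4, the 4-leaf star
and P3.

### Small-world normalization

γ = Cp/⟨Cp_rand⟩ and λ = Lp/⟨Lp_rand⟩ normalize against an ensemble of
Maslov–Sneppen degree-preserving rewired graphs (default 100 nulls,
10 × edge-count swap attempts each; the null construction is rarely
specified in applied papers, and degree-preserving rewiring is the standard
choice because degree sequence is the first-order confound of clustering
and path length). σ = γ/λ > 1 indicates small-world organization. The
complete graph is a fixed point (no legal swap exists), giving
γ = λ = σ = 1 exactly; an Erdős–Rényi graph is statistically its own null,
giving γ, λ ≈ 1 — both are asserted in the suite.

### Permutation inference

Each group yields one network per sparsity, so group comparison of network
metrics has no subject-level sampling distribution; inference is by random
relabelling of group membership (sizes preserved). The test statistic is
the **area under the metric's sparsity curve** (trapezoid over the grid):
published analyses report one p per metric without stating how the sweep is
collapsed, and the AUC is the summary that uses the whole sweep without
privileging any sparsity. Per-sparsity curves remain available in the
report bundle for inspection. The empirical two-tailed p uses the add-one
convention `p = (1 + #{|null| ≥ |obs|})/(1 + n_perm)`, so p is never 0 and
its floor is 1/(n_perm + 1). Nodal tests share one set of relabellings
across nodes, preserving the cross-node dependence of the null for the
subsequent FDR step. The default is 5,000 relabellings for real runs; the
test suite and acceptance script use 200 with correspondingly coarse
Monte-Carlo resolution (the attainable p floor is then ≈ 0.005).

A genuine limitation surfaced during development: with fixed-K
binarization the permutation null of a topology statistic is *not* simply
an attenuated version of the observed contrast. Rank thresholding is
winner-take-all — a relabelled group inherits whichever correlation
structure dominates its mixture — so "the observed difference exceeds
every relabelled difference" cannot be engineered robustly for network
statistics, and the minimal attainable p is demonstrated instead on the
continuous edge statistic, where mixtures provably attenuate. For the
network tests the suite verifies the add-one formula, the floor, the
relabelling symmetry, and type-I calibration.

## 2. The synthetic cohort generator

`generate_cohort()` draws the control group from a multivariate Gaussian
over regions with mean 1 (SUV ratios), regional SD 0.1, and a base
correlation structure `r_ij = max(0.6^(1+|i−j|/10), 0.2)` repaired to the
nearest positive semidefinite correlation matrix — smoothly decaying
coupling over a uniformly positive floor, mimicking the broadly positive,
spatially structured correlation matrices of metabolic data. The patient
group shares this structure with two plants:

* a seed-region mean shift (default +0.05 = 0.5 regional SD at the right
  postcentral gyrus), and
* four seed–target edges (right caudate, left amygdala, left hippocampus,
  left supramarginal gyrus) set to r = 0.6 in both groups and reduced to
  r = 0.2 in the patient group.

Biomarkers are generated by Gaussian-copula conditioning on the
standardized seed SUV in the patient group (defaults r(AST) = −0.277,
r(PT) = +0.256; independent in controls), ages ~ N(54, 8) vs N(50, 6), BMI
~ N(24.3, 2.5) vs N(23.5, 2.5), and binary demographics hit their
configured 2×2 counts exactly (defaults emulate a 70/70 lacunar-stroke
case-control table: smoking 10 vs 1, hypertension 23 vs 13, male 52 vs 42,
…). One root seed derives named per-component streams, all recorded in the
output, so every draw is reproducible and components can be regenerated
independently.

Published case-control tables rarely include SUV variances or effect
sizes, so the generator's effect magnitudes (SD 0.1, shift 0.5 SD, edge
drop 0.6 → 0.2) are documented placeholders chosen once at what a
practitioner would call a moderate, realistic scale — they are the study
conditions of all downstream tests and are not adjusted to make tests
pass.

**What the generator does not emulate:** voxel-level PET noise, partial
volume effects, scanner and attenuation artefacts, spatial smoothing,
non-Gaussian SUV marginals, site or batch structure. Passing tests
therefore demonstrate the *statistical machinery* — calibration,
invariants, recovery of planted structure — not robustness to PET physics.

### Power at the planted effect sizes

An independent power simulation (200 replicates at the default design,
n = 70/group) run before freezing any thresholds gave: probability that
the seed region tops the regional ranking ≈ 0.66; per-edge Fisher-z power
after BH over 89 edges ≈ 0.4 (a 0.6 → 0.2 drop at n = 70 is a z of only
≈ 2.8, while the BH threshold at rank 4/89 needs ≈ 3.1); probability of
recovering ≥ 3 of 4 edges at q < 0.05 ≈ 0.09; ≥ 1 of 4 ≈ 0.49. The frozen
regression thresholds — seed-top rate ≥ 0.45 and ≥ 1-edge recovery rate
≥ 0.30 over 50 replicates — sit ≈ 3 binomial SDs below those rates. Full
recovery of all four edges at FDR 0.05 would need either n ≈ 200/group or
a larger planted decorrelation; the package reports what the configured
conditions support rather than inflating the plant.

## 3. Numerical choices

* **PSD repair** (`nearest_correlation()`): eigenvalue clipping at 0 with
  diagonal rescaling, iterated to min eigenvalue ≥ −1e−8. For matrices
  already PSD the input is returned unchanged; planted targets are then
  hit exactly. Cross-checked against an alternating-projection oracle.
* **Degenerate inputs**: empty graphs give all-zero metrics with a
  warning; sparsity grids are validated (0 < min < max < 1, step > 0)
  before any computation; K = 0 thresholds, |r| = 1 in the z transform,
  zero-margin contingency tables, and rank-deficient GLM designs raise
  descriptive errors.
* **Determinism**: identical configuration + seed reproduces every
  numeric output byte-identically; rewiring, permutation and generation
  streams are all derived from explicit seeds.
* **Demographic χ²** is the uncorrected Pearson form by default — the
  form under which published 2×2 statistics of this kind reproduce to
  3 d.p. — with Yates correction behind a flag. Summary t-tests accept
  mean/SE/n (use SE = SD/√n for SD-style tables; note that some published
  "mean ± SD" age rows are only consistent with the printed t when read
  as mean ± SE). The Mann–Whitney implementation exposes the
  tie-corrected normal z, validated against exact enumeration at small n.

## 4. Problem sizes used by the test suite

The suite and acceptance script scale the study down where the full design
would add nothing but runtime: permutation calibration uses 10 regions,
30/group, 200 relabellings, 100 replicates, on a 0.10–0.50 step-0.05 grid;
planted-effect recovery uses the full 90-region, 70/group design over 50
replicates; the Fisher-z/permutation cross-check uses 10,000 relabellings.
These sizes are the package's chosen validation design and are stated here
so users can reproduce them exactly.

## 5. Known limitations

* Group-level connectivity cannot be attached to individual subjects; all
  network inference is about group ensembles.
* The Fisher z edge test assumes bivariate normality within groups; the
  permutation alternative relaxes this at computational cost.
* Lp's connected-pairs convention makes path length non-comparable across
  graphs with very different connected fractions; compare Eglob alongside.
* No partial correlations, no weighted-graph metrics, no community or
  rich-club analysis, and no spatial preprocessing (normalization,
  smoothing, motion/attenuation correction) — inputs are assumed already
  parcellated or parcellation-ready.
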