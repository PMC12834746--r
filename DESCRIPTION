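Package: metaconn
Title: Group-Level Metabolic Connectivity and Brain Network Analysis for PET SUV Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for group-level metabolic connectomics from atlas-parcellated
    FDG-PET uptake: whole-brain-normalized standardized uptake value (SUV)
    extraction, cross-subject Pearson metabolic connectivity with seed-based
    edge tests and false-discovery-rate control, sparsity-swept binary network
    construction with graph-theoretic characterization (clustering, path
    length, efficiency, small-worldness against degree-preserving rewired
    nulls), non-parametric permutation inference for group differences in
    network metrics, demographic and biomarker statistics, and a synthetic
    cohort generator that emulates the statistical structure such studies
    assume so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    MASS,
    stats,
    utils,
    jsonlite,
    yaml,
    pracma,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
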