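Package: mitocn
Title: Mitochondrial DNA Copy Number Estimation and Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate relative mitochondrial DNA copy number from
    off-target sequencing depth, adjust it for blood-cell composition, and
    test its genetic and phenotypic correlates in admixed cohorts. Includes
    phenome-wide association scans with false-discovery-rate control,
    admixture mapping with an empirical multiple-testing burden, Haseman-
    Elston and average-information REML heritability estimation, polygenic
    scoring, replication power calculations, and mito-nuclear interaction
    tests with simulation-based power analysis. A synthetic-cohort generator
    reproduces the statistical structure these analyses assume, so the whole
    pipeline runs and is testable without restricted individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
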