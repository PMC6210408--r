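Package: segcca
Title: Global-to-Local Multivariate Genotype-Phenotype Association for Dense
    3D Landmark Shape Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a global-to-local pipeline for testing the association
    between single genetic variants and multivariate shape phenotypes measured
    as spatially dense 3D landmark configurations. Provides generalized
    Procrustes superimposition, symmetrization and Mahalanobis quality
    flagging; partial least-squares residualization of shape and genotype on
    confounders; hierarchical spectral segmentation of landmarks driven by
    Escoufier RV covariation; per-segment principal component analysis with
    Horn-style parallel analysis; canonical-correlation association tests with
    the Rao F approximation; projection-based round-robin replication across
    cohorts combined by Stouffer meta-analysis; and Li-Ji
    effective-number-of-tests Bonferroni correction. A synthetic-data module
    generates correspondence-matched multi-cohort landmark panels with
    covariate effects and localized additive SNP effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
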