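Package: growthmicro
Title: Early-Childhood Growth Trajectories and Microbiota Composition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical machinery linking early-childhood growth
    trajectories to oral and gut microbiota composition. Implements
    conditional weight gain (CWG) z-scores from LMS growth references,
    sparse functional principal component analysis (PACE-style) for
    reconstructing smooth weight-for-length growth curves from sparse
    clinic visits, penalized function-on-scalar regression with L2, PCA
    and Choi quadratic-form significance measures, phylogeny-guided
    two-stage aggregation of genus-level 16S abundance counts into
    taxonomic groups, adaptive RKHS-penalized functional variable
    selection (a FLAME-style estimator with a Sobolev kernel), diversity
    summaries (inverse Simpson, Shannon, Firmicutes:Bacteroidetes ratio),
    covariate pruning and exhaustive best-subset regression, and a
    synthetic mother-child cohort generator with known ground truth so
    that every stage is testable without access to restricted cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    grDevices,
    graphics,
    ape,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
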