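Package: wingmorph
Title: Geometric Morphometrics of the Developing Drosophila Wing
Version: 0.1.0
Authors@R:
    person("Morphometrics", "Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Landmark-based analysis of wing shape and size across
    developmental stages (third-instar larval disc, 5 h pupal wing, adult
    wing) and genotypes. Provides TPS/CSV landmark ingestion, generalized
    Procrustes superimposition with chord-tangent semilandmark sliding,
    tangent-space adequacy checks, principal component and canonical
    variate ordination, randomization MANOVA on Wilks' lambda via
    mean-residual decomposition, robust (minimum covariance determinant)
    multivariate outlier screening, Grubbs univariate size screening,
    scalar measures (standardized inter-landmark distances, margin
    lengths, surveyor's-formula polygon areas, centroid size), bootstrap
    ratio-of-means comparisons with delta-method standard errors, and a
    synthetic-data generator emulating the sampling design so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
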